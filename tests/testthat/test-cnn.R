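test_that("stratified split respects per-class floor(0.8 n) and the seed", {
  labs <- rep(c("fetal", "laugh", "respiratory"), each = 100)
  sp <- stratified_split(labs, 0.8, seed = 1)
  for (cl in unique(labs)) {
    expect_equal(sum(labs[sp$train_idx] == cl), 80)
    expect_equal(sum(labs[sp$test_idx] == cl), 20)
  }
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_setequal(c(sp$train_idx, sp$test_idx), seq_along(labs))
  expect_identical(sp, stratified_split(labs, 0.8, seed = 1))
  expect_false(identical(sp$train_idx,
                         stratified_split(labs, 0.8, seed = 2)$train_idx))

  # the clinical class totals under the floor rule
  labs2 <- rep(c("fetal", "laugh", "respiratory"), c(1022, 276, 1563))
  sp2 <- stratified_split(labs2, 0.8, seed = 3)
  expect_equal(sum(labs2[sp2$train_idx] == "fetal"), floor(0.8 * 1022))
  expect_equal(sum(labs2[sp2$train_idx] == "laugh"), floor(0.8 * 276))
  expect_equal(sum(labs2[sp2$train_idx] == "respiratory"), floor(0.8 * 1563))

  expect_error(stratified_split(c("fetal", "laugh")), "at least 2")
})

test_that("parameter count matches the closed-form layer arithmetic", {
  m <- build_cnn(cnn_spec(), c(64, 26, 3), seed = 1)
  conv1 <- (5 * 3 * 3 + 1) * 60
  conv2 <- (5 * 2 * 60 + 1) * 50
  conv3 <- (5 * 2 * 50 + 1) * 40
  h_out <- 64 - 5 + 1 - 5 + 1 - 5 + 1   # 52
  w_out <- 26 - 3 + 1 - 2 + 1 - 2 + 1   # 22
  dense <- (h_out * w_out * 40 + 1) * 3
  expect_equal(n_params(m), conv1 + conv2 + conv3 + dense)
})

test_that("model building is seed-deterministic and shape-checked", {
  m1 <- build_cnn(cnn_spec_small(), c(64, 26, 3), seed = 9)
  m2 <- build_cnn(cnn_spec_small(), c(64, 26, 3), seed = 9)
  expect_identical(m1$layers, m2$layers)
  expect_identical(m1$dense, m2$dense)
  expect_error(build_cnn(cnn_spec(), c(8, 4, 1), seed = 1),
               class = "fetmov_shape_error")

  # kernel adaptation lets the H-matrix input (5 x 26) through
  ker <- adapt_kernels(c(5, 26, 3), cnn_spec()$conv_kernels)
  expect_equal(ker[[1]], c(5, 3))
  expect_equal(ker[[2]], c(1, 2))
  expect_equal(ker[[3]], c(1, 2))
  spec <- cnn_spec_small(); spec$conv_kernels <- ker
  expect_s3_class(build_cnn(spec, c(5, 26, 3), seed = 1), "fetmov_cnn")
})

test_that("prediction rows are probabilities and argmax matches labels", {
  spec <- cnn_spec_small(epochs = 1L)
  m <- build_cnn(spec, c(16, 8, 1), seed = 2)
  set.seed(3)
  X <- matrix(rnorm(128 * 12), 128, 12)
  pr <- predict(m, X)
  expect_equal(unname(rowSums(pr$probs)), rep(1, 12), tolerance = 1e-6)
  expect_true(all(pr$probs >= 0))
  expect_identical(as.integer(pr$labels),
                   unname(apply(pr$probs, 1, which.max)))
  expect_error(predict(m, X[1:10, , drop = FALSE]),
               class = "fetmov_shape_error")
})

test_that("training is deterministic and learns a single-class problem", {
  spec <- cnn_spec_small(epochs = 2L, learning_rate = 0.2, batch_size = 16L)
  m <- build_cnn(spec, c(16, 8, 1), seed = 4)
  set.seed(5)
  X <- matrix(runif(128 * 64), 128, 64)
  labs <- factor(rep("laugh", 64), levels = fetmov:::fm_classes())
  t1 <- train_cnn(m, X, labs, seed = 6)
  t2 <- train_cnn(m, X, labs, seed = 6)
  expect_identical(t1$training_log, t2$training_log)
  expect_identical(t1$layers, t2$layers)
  pr <- predict(t1, X)
  expect_true(all(pr$labels == "laugh"))
})

test_that("a separable toy problem is learned to high training accuracy", {
  # class-distinct constant blocks
  set.seed(7)
  n_per <- 30
  mk <- function(hot) {
    img <- matrix(0.05, 18, 10)
    rows <- list(1:6, 7:12, 13:18)[[hot]]
    img[rows, ] <- 0.9
    as.vector(img) + rnorm(180, 0, 0.02)
  }
  X <- sapply(rep(1:3, each = n_per), mk)
  labs <- factor(rep(fetmov:::fm_classes(), each = n_per))
  spec <- cnn_spec_small(epochs = 10L, learning_rate = 0.05)
  m <- build_cnn(spec, c(18, 10, 1), seed = 8)
  tr <- train_cnn(m, X, labs, seed = 9)
  acc <- mean(predict(tr, X)$labels == labs)
  expect_gte(acc, 0.95)
  # loss mostly decreases across epochs
  expect_gte(mean(diff(tr$training_log) <= 0), 0.9)
})
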