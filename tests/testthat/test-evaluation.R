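test_that("confusion_matrix3 counts true/predicted pairs", {
  cls <- c("fetal", "laugh", "respiratory")
  perfect <- sample(rep(cls, 10))
  cm <- confusion_matrix3(perfect, perfect)
  expect_equal(unname(diag(unclass(cm))), rep(10L, 3))
  expect_equal(sum(unclass(cm)), 30)

  cm2 <- confusion_matrix3(cls[c(1, 1, 2, 3)], cls[c(1, 2, 2, 3)])
  m <- unclass(cm2)
  expect_equal(m["fetal", "laugh"], 1L)
  expect_equal(unname(diag(m)), c(1L, 1L, 1L))

  empty <- confusion_matrix3(character(), character())
  expect_true(all(unclass(empty) == 0))
  expect_error(confusion_matrix3("fetal", "cough"), "outside")
  expect_error(confusion_matrix3(cls, cls[1:2]), "equal length")
})

test_that("per_class_rates implements one-vs-rest TPR/FPR", {
  cm <- matrix(c(10, 0, 0, 0, 10, 0, 0, 0, 10), 3, byrow = TRUE)
  r <- per_class_rates(cm)
  expect_equal(r$tpr, rep(1, 3))
  expect_equal(r$fpr, rep(0, 3))

  cm2 <- matrix(c(86, 7, 7, 10, 80, 10, 4, 4, 92), 3, byrow = TRUE)
  r2 <- per_class_rates(cm2)
  expect_equal(r2$tpr[1], 0.86)
  expect_equal(r2$fpr[1], 14 / 200)

  # brute-force definition oracle on random matrices
  set.seed(2)
  for (rep in 1:10) {
    m <- matrix(rpois(9, 20), 3, 3)
    r <- per_class_rates(m)
    for (c in 1:3) {
      expect_equal(r$tpr[c], m[c, c] / sum(m[c, ]))
      expect_equal(r$fpr[c],
                   (sum(m[, c]) - m[c, c]) / (sum(m) - sum(m[c, ])))
    }
  }

  # empty true row: flagged undefined, not NaN
  cm3 <- matrix(c(0, 0, 0, 1, 5, 0, 2, 0, 9), 3, byrow = TRUE)
  r3 <- per_class_rates(cm3)
  expect_true(is.na(r3$tpr[1]))
  expect_false(r3$defined[1])
  expect_false(anyNA(r3$fpr))
})

test_that("agreement_table reproduces the printed three-method percentages", {
  truth <- 30 * (1:90)
  device <- truth[1:73] + 1     # all-three (59) + ultrasound+device (14)
  mother <- truth[1:59] + 2     # all-three only
  tab <- agreement_table(truth, device, mother, match_tol_s = 5)
  get <- function(d, m) tab$percent[tab$device == d & tab$mother == m]
  expect_equal(get(0, 0), 18.89)
  expect_equal(get(1, 0), 15.56)
  expect_equal(get(1, 1), 65.56)
  expect_equal(tab$n[order(tab$device, tab$mother)], c(17L, 14L, 59L))
  expect_lt(abs(sum(tab$percent) - 100), 0.05)
})

test_that("agreement matching is one-to-one within tolerance", {
  # everything detected by everyone: a single pattern at 100%
  truth <- c(10, 40, 70)
  tab <- agreement_table(truth, truth + 0.5, truth - 0.5)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$percent, 100)
  expect_equal(tab$device, 1L)

  # a device event 10 s away from every truth event does not match at 5 s
  tab2 <- agreement_table(c(100, 200), c(110, 210), numeric(0))
  expect_true(all(tab2$device == 0))

  # brute-force matcher oracle on random event sets
  set.seed(4)
  for (rep in 1:50) {
    truth <- sort(runif(8, 0, 400))
    cand <- sort(runif(6, 0, 400))
    got <- fetmov:::match_events(truth, cand, 5)
    # oracle: greedy over all pairs by distance
    pairs <- expand.grid(ti = 1:8, ci = 1:6)
    pairs$d <- abs(truth[pairs$ti] - cand[pairs$ci])
    pairs <- pairs[pairs$d <= 5, ]
    pairs <- pairs[order(pairs$d), ]
    want <- rep(FALSE, 8); used <- rep(FALSE, 6)
    for (r in seq_len(nrow(pairs))) {
      if (!want[pairs$ti[r]] && !used[pairs$ci[r]]) {
        want[pairs$ti[r]] <- TRUE; used[pairs$ci[r]] <- TRUE
      }
    }
    expect_identical(got, want)
  }

  expect_error(agreement_table(numeric(0), 1, 1), "empty")
})

test_that("class_count_table reproduces the clinical tabulation", {
  rows <- list(`29` = c(174, 35, 263), `33` = c(265, 78, 360),
               `38` = c(583, 163, 954))
  labels <- character(0); ages <- numeric(0)
  for (age in names(rows)) {
    n <- rows[[age]]
    labels <- c(labels, rep(c("fetal", "laugh", "respiratory"), n))
    ages <- c(ages, rep(as.numeric(age), sum(n)))
  }
  tab <- class_count_table(labels, ages)
  expect_equal(tab$fetal, c(174, 265, 583, 1022))
  expect_equal(tab$laugh, c(35, 78, 163, 276))
  expect_equal(tab$respiratory, c(263, 360, 954, 263 + 360 + 954))
  # totals equal independent column sums
  for (cl in c("fetal", "laugh", "respiratory")) {
    expect_equal(tab[[cl]][4], sum(tab[[cl]][1:3]))
  }

  # empty bins are retained as zero rows
  t2 <- class_count_table(c("fetal", "fetal"), c(29, 29))
  expect_equal(t2$fetal, c(2, 0, 0, 2))

  expect_error(class_count_table("fetal", 20), "26")
})

test_that("evaluation is invariant to realization order", {
  set.seed(5)
  cls <- fetmov:::fm_classes()
  truth <- sample(cls, 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.8, truth, sample(cls, 60, replace = TRUE))
  perm <- sample(60)
  expect_identical(unclass(confusion_matrix3(truth, pred)),
                   unclass(confusion_matrix3(truth[perm], pred[perm])))
})
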