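#' Specification of the small convolutional classifier
#'
#' The network is deliberately shallow to keep the computational burden
#' low: three valid (unpadded) convolution stages with ReLU activations,
#' followed by a flatten and a single dense softmax head over the three
#' classes. The reference configuration uses kernels 5x3, 5x2, 5x2 with
#' 60, 50 and 40 filters and plain stochastic gradient descent at learning
#' rate 1e-4. All of it is configurable; smaller filter counts and fewer
#' epochs are appropriate for the synthetic corpora bundled with the
#' package, which are far easier than clinical data.
#'
#' @param conv_kernels List of three `c(height, width)` kernel sizes.
#' @param conv_filters Integer vector of three filter counts.
#' @param learning_rate SGD learning rate.
#' @param epochs Training epochs (full passes).
#' @param batch_size Minibatch size.
#' @param n_classes Number of output classes (3).
#' @return A `fetmov_cnn_spec` list.
#' @export
cnn_spec <- function(conv_kernels = list(c(5L, 3L), c(5L, 2L), c(5L, 2L)),
                     conv_filters = c(60L, 50L, 40L),
                     learning_rate = 1e-4, epochs = 300L, batch_size = 32L,
                     n_classes = 3L) {
  if (length(conv_kernels) != 3L || length(conv_filters) != 3L) {
    abort("the architecture has exactly three convolution stages")
  }
  assert_scalar_num(learning_rate, "learning_rate", lo = 1e-12)
  assert_scalar_num(epochs, "epochs", lo = 1)
  assert_scalar_num(batch_size, "batch_size", lo = 1)
  structure(
    list(conv_kernels = lapply(conv_kernels, as.integer),
         conv_filters = as.integer(conv_filters),
         activation = "relu", optimizer = "sgd",
         learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         n_classes = as.integer(n_classes)),
    class = "fetmov_cnn_spec"
  )
}

#' Desk-scale classifier configuration
#'
#' The reference architecture (60/50/40 filters, 300 epochs at lr 1e-4) is
#' sized for a clinical corpus. The bundled synthetic corpora are smaller
#' and much easier, so the package's own experiments use this lighter
#' configuration: 8/6/4 filters trained for 10 epochs at lr 0.01, same
#' three-stage architecture and optimizer.
#'
#' @inheritParams cnn_spec
#' @return A `fetmov_cnn_spec`.
#' @export
cnn_spec_small <- function(conv_filters = c(8L, 6L, 4L),
                           learning_rate = 0.01, epochs = 10L,
                           batch_size = 32L) {
  cnn_spec(conv_filters = conv_filters, learning_rate = learning_rate,
           epochs = epochs, batch_size = batch_size)
}

#' Clip kernel sizes to fit a small input
#'
#' The NNMF-factor inputs (`W`: 64 x rank, `H`: rank x 26) can be narrower
#' or shorter than the default kernels; this helper shrinks each kernel
#' dimension to the spatial extent still available at its stage, keeping
#' the three-stage architecture intact across algorithm variants.
#'
#' @param input_shape `c(height, width, channels)`.
#' @param kernels List of three `c(h, w)` kernels.
#' @return List of three adapted kernels.
#' @export
adapt_kernels <- function(input_shape, kernels) {
  h <- input_shape[1]; w <- input_shape[2]
  out <- vector("list", length(kernels))
  for (l in seq_along(kernels)) {
    kh <- min(kernels[[l]][1], h)
    kw <- min(kernels[[l]][2], w)
    out[[l]] <- c(kh, kw)
    h <- h - kh + 1L
    w <- w - kw + 1L
  }
  out
}

# im2col plan for one valid-convolution stage: linear indices into the
# flattened (h, w, c) column-major input, one column per output location.
conv_plan <- function(in_h, in_w, in_c, kh, kw) {
  out_h <- in_h - kh + 1L
  out_w <- in_w - kw + 1L
  if (out_h < 1L || out_w < 1L) {
    abort("input smaller than the kernel at some stage", class = "fetmov_shape_error")
  }
  off <- as.vector(outer(
    as.vector(outer(0:(kh - 1L), (0:(kw - 1L)) * in_h, `+`)),
    (seq_len(in_c) - 1L) * in_h * in_w, `+`
  ))
  base <- as.vector(outer(seq_len(out_h), (seq_len(out_w) - 1L) * in_h, `+`))
  idx <- outer(off, base, `+`)
  list(iv = as.integer(idx),
       K = kh * kw * in_c, L = out_h * out_w,
       out_h = out_h, out_w = out_w, in_len = in_h * in_w * in_c)
}

#' Build an untrained convolutional classifier
#'
#' Lays out the three conv stages for the given input shape (erroring when
#' a spatial dimension falls below a kernel size) and initializes weights
#' from a seeded He-scaled normal.
#'
#' @param spec A [cnn_spec()].
#' @param input_shape `c(height, width, channels)` of one feature array.
#' @param seed Integer seed for the initialization.
#' @return A `fetmov_cnn` model (untrained).
#' @export
build_cnn <- function(spec = cnn_spec(), input_shape, seed = 1L) {
  stopifnot(inherits(spec, "fetmov_cnn_spec"))
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3L) abort("input_shape must be (h, w, channels)")
  h <- input_shape[1]; w <- input_shape[2]; cin <- input_shape[3]
  plans <- vector("list", 3L)
  layers <- vector("list", 3L)
  with_seed(seed, {
    for (l in 1:3) {
      kh <- spec$conv_kernels[[l]][1]; kw <- spec$conv_kernels[[l]][2]
      f <- spec$conv_filters[l]
      plans[[l]] <- conv_plan(h, w, cin, kh, kw)
      fan_in <- kh * kw * cin
      layers[[l]] <- list(
        W = matrix(rnorm(f * fan_in, 0, sqrt(2 / fan_in)), f, fan_in),
        b = numeric(f)
      )
      h <- plans[[l]]$out_h; w <- plans[[l]]$out_w; cin <- f
    }
    d_flat <- h * w * cin
    dense <- list(
      W = matrix(rnorm(spec$n_classes * d_flat, 0, sqrt(2 / d_flat)),
                 spec$n_classes, d_flat),
      b = numeric(spec$n_classes)
    )
    structure(
      list(spec = spec, input_shape = input_shape, plans = plans,
           layers = layers, dense = dense, class_order = fm_classes(),
           trained = FALSE, training_log = numeric()),
      class = "fetmov_cnn"
    )
  })
}

#' Number of trainable parameters
#' @param model A `fetmov_cnn`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "fetmov_cnn"))
  sum(vapply(model$layers, function(l) length(l$W) + length(l$b), 0)) +
    length(model$dense$W) + length(model$dense$b)
}

# Forward pass. X: (h*w*c) x B matrix of flattened inputs (column-major
# h-fastest layout). Returns cache for backprop when `keep = TRUE`.
cnn_forward <- function(model, X, keep = FALSE) {
  B <- ncol(X)
  cache <- if (keep) list(inputs = vector("list", 3L),
                          relu = vector("list", 3L)) else NULL
  A <- X
  for (l in 1:3) {
    pl <- model$plans[[l]]
    P <- im2col_gather(A, pl$iv)
    dim(P) <- c(pl$K, pl$L * B)
    Z <- model$layers[[l]]$W %*% P + model$layers[[l]]$b
    R <- Z > 0
    Z[!R] <- 0
    if (keep) {
      cache$inputs[[l]] <- P
      cache$relu[[l]] <- R
    }
    f <- nrow(Z)
    dim(Z) <- c(f, pl$L, B)
    Z <- aperm(Z, c(2L, 1L, 3L))
    dim(Z) <- c(pl$L * f, B)
    A <- Z
  }
  logits <- model$dense$W %*% A + model$dense$b
  if (keep) cache$flat <- A
  mx <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, mx))
  probs <- sweep(e, 2, colSums(e), `/`)
  list(probs = probs, logits = logits, cache = cache)
}

# One SGD step on a minibatch; returns the updated model and the batch loss.
cnn_sgd_step <- function(model, X, y_onehot, lr) {
  B <- ncol(X)
  fw <- cnn_forward(model, X, keep = TRUE)
  loss <- -mean(colSums(y_onehot * log(pmax(fw$probs, 1e-12))))
  dlogits <- (fw$probs - y_onehot) / B
  model$dense$b <- model$dense$b - lr * rowSums(dlogits)
  dflat <- crossprod(model$dense$W, dlogits)
  model$dense$W <- model$dense$W - lr * tcrossprod(dlogits, fw$cache$flat)
  dY <- dflat
  for (l in 3:1) {
    pl <- model$plans[[l]]
    f <- nrow(model$layers[[l]]$W)
    dim(dY) <- c(pl$L, f, B)
    dZ <- aperm(dY, c(2L, 1L, 3L))
    dim(dZ) <- c(f, pl$L * B)
    dZ[!fw$cache$relu[[l]]] <- 0
    P <- fw$cache$inputs[[l]]
    dW <- tcrossprod(dZ, P)
    db <- rowSums(dZ)
    if (l > 1L) {
      dP <- crossprod(model$layers[[l]]$W, dZ)
      dim(dP) <- c(pl$K * pl$L, B)
      dY <- im2col_scatter(dP, pl$iv, pl$in_len)
    }
    model$layers[[l]]$W <- model$layers[[l]]$W - lr * dW
    model$layers[[l]]$b <- model$layers[[l]]$b - lr * db
  }
  list(model = model, loss = loss)
}

#' Stratified train/test split
#'
#' Random split preserving the inter-class ratio: within each class,
#' `floor(train_frac * n)` realizations go to training and the rest to
#' testing, under a fixed seed.
#'
#' @param labels Factor (or character) of class labels.
#' @param train_frac Training fraction per class (default 0.8).
#' @param seed Integer seed.
#' @return List with integer `train_idx` and `test_idx`.
#' @export
#' @examples
#' sp <- stratified_split(rep(c("fetal", "laugh", "respiratory"), each = 10),
#'                        seed = 1)
#' lengths(sp)
stratified_split <- function(labels, train_frac = 0.8, seed = 1L) {
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  tab <- table(labels)
  if (any(tab < 2L)) abort("every class needs at least 2 realizations")
  assert_scalar_num(train_frac, "train_frac", lo = 1e-9, hi = 1)
  with_seed(seed, {
    train_idx <- integer(0)
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      n_tr <- floor(train_frac * length(idx))
      train_idx <- c(train_idx, sample(idx, n_tr))
    }
    train_idx <- sort(train_idx)
    list(train_idx = train_idx,
         test_idx = setdiff(seq_along(labels), train_idx))
  })
}

#' Train the convolutional classifier
#'
#' Plain minibatch stochastic gradient descent on the softmax
#' cross-entropy, with seeded shuffling each epoch. Aborts if the loss
#' turns non-finite.
#'
#' @param model An untrained `fetmov_cnn` from [build_cnn()].
#' @param X Feature matrix, `prod(input_shape)` rows by one column per
#'   realization (see [featurize()]).
#' @param labels Factor of class labels, one per column of `X`.
#' @param train_idx Indices (columns) to train on; default all.
#' @param seed Integer seed for shuffling.
#' @return The trained `fetmov_cnn`, with per-epoch mean loss in
#'   `$training_log`.
#' @export
train_cnn <- function(model, X, labels, train_idx = NULL, seed = 1L) {
  stopifnot(inherits(model, "fetmov_cnn"))
  if (nrow(X) != prod(model$input_shape)) {
    abort("feature rows do not match the model input shape",
          class = "fetmov_shape_error")
  }
  labels <- factor(as.character(labels), levels = model$class_order)
  if (anyNA(labels)) abort("labels outside the model's class set")
  train_idx <- train_idx %||% seq_len(ncol(X))
  if (!length(train_idx)) abort("empty training split")
  spec <- model$spec
  y_all <- diag(spec$n_classes)[, as.integer(labels), drop = FALSE]
  log_loss <- numeric(spec$epochs)
  with_seed(seed, {
    for (ep in seq_len(spec$epochs)) {
      ord <- sample(train_idx)
      losses <- c()
      for (start in seq(1L, length(ord), by = spec$batch_size)) {
        bi <- ord[start:min(length(ord), start + spec$batch_size - 1L)]
        st <- cnn_sgd_step(model, X[, bi, drop = FALSE],
                           y_all[, bi, drop = FALSE], spec$learning_rate)
        if (!is.finite(st$loss)) {
          abort(sprintf("training diverged (non-finite loss at epoch %d)", ep))
        }
        model <- st$model
        losses <- c(losses, st$loss)
      }
      log_loss[ep] <- mean(losses)
    }
  })
  model$trained <- TRUE
  model$training_log <- log_loss
  model
}

#' Predict realization classes
#'
#' @param object A trained `fetmov_cnn`.
#' @param X Feature matrix (same layout as in [train_cnn()]).
#' @param ... Unused.
#' @return A list with `labels` (factor in the model's class order; ties
#'   resolve to the lowest class index) and `probs` (matrix, one row per
#'   realization, rows summing to 1).
#' @export
predict.fetmov_cnn <- function(object, X, ...) {
  if (nrow(X) != prod(object$input_shape)) {
    abort("feature rows do not match the model input shape",
          class = "fetmov_shape_error")
  }
  probs <- t(cnn_forward(object, X)$probs)
  colnames(probs) <- object$class_order
  labels <- factor(object$class_order[max.col(probs, ties.method = "first")],
                   levels = object$class_order)
  list(labels = labels, probs = probs)
}

#' @export
print.fetmov_cnn <- function(x, ...) {
  cat(sprintf("<fetmov_cnn> input %s, filters %s, %s, %d parameters\n",
              paste(x$input_shape, collapse = "x"),
              paste(x$spec$conv_filters, collapse = "/"),
              if (x$trained) "trained" else "untrained", n_params(x)))
  invisible(x)
}
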