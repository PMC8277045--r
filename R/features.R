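# STFT geometry: a 200-sample realization is zero-padded to 201 samples and
# analysed with a 126-sample Hann window hopped by 3 samples, one-sided FFT
# of length 126. That yields exactly 64 frequency bins x 26 time frames --
# the classifier's fixed input size -- with no resampling.
stft_win_len <- 126L
stft_hop <- 3L
stft_pad_to <- 201L
stft_n_freq <- 64L   # 126/2 + 1
stft_n_frames <- 26L # floor((201 - 126)/3) + 1

#' Magnitude spectrogram of a realization
#'
#' Computes the short-time Fourier magnitude of one 200-sample realization:
#' symmetric Hann window of 126 samples, hop 3, zero-padding to 201
#' samples, one-sided spectrum. The result is the non-negative 64 x 26
#' matrix `V` (frequency rows by time columns) consumed by the classifier
#' and by [nnmf_factorize()].
#'
#' @param samples Numeric vector of exactly 200 samples (one realization),
#'   or a one-row realization tibble from [extract_window()].
#' @param fs Sampling rate in samples/s (for the bin-frequency labels).
#' @return A `fetmov_spectrogram`: list with `V` (64 x 26), `freq_hz`
#'   (64 bin centres) and `frame_start` (26 window starts, 1-based).
#' @export
#' @examples
#' sp <- stft_magnitude(sin(2 * pi * 40 * (0:199) / 280))
#' dim(sp$V)
stft_magnitude <- function(samples, fs = 280) {
  if (is.data.frame(samples)) samples <- samples$samples[[1]]
  samples <- as.numeric(samples)
  if (length(samples) != realization_window_width) {
    abort(sprintf("a realization has exactly %d samples",
                  realization_window_width))
  }
  x <- c(samples, numeric(stft_pad_to - length(samples)))
  w <- hann_window(stft_win_len)
  starts <- 1L + stft_hop * (seq_len(stft_n_frames) - 1L)
  V <- matrix(0, stft_n_freq, stft_n_frames)
  for (j in seq_len(stft_n_frames)) {
    seg <- x[starts[j]:(starts[j] + stft_win_len - 1L)] * w
    V[, j] <- Mod(fft(seg)[seq_len(stft_n_freq)])
  }
  structure(
    list(V = V,
         freq_hz = (seq_len(stft_n_freq) - 1L) * fs / stft_win_len,
         frame_start = starts),
    class = "fetmov_spectrogram"
  )
}

# Symmetric Hann window.
hann_window <- function(n) {
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))
}

#' The package's fixed spectrogram colour lookup table
#'
#' 256 RGB entries in `[0, 1]`, built once from fixed anchor colours by
#' linear interpolation, with strictly increasing luminance so that larger
#' magnitudes always render brighter. Shipping the table as a deterministic
#' function of nothing keeps rendered images bit-stable across platforms.
#'
#' @return A 256 x 3 numeric matrix (columns R, G, B).
#' @export
spectrogram_lut <- function() {
  anchors <- rbind(
    c(0.00, 0.00, 0.00),
    c(0.10, 0.05, 0.35),
    c(0.45, 0.10, 0.50),
    c(0.85, 0.35, 0.20),
    c(0.99, 0.91, 0.25),
    c(1.00, 1.00, 0.95)
  )
  pos <- seq(0, 1, length.out = nrow(anchors))
  grid <- seq(0, 1, length.out = 256L)
  lut <- sapply(1:3, function(ch) {
    stats::approx(pos, anchors[, ch], xout = grid)$y
  })
  colnames(lut) <- c("r", "g", "b")
  lut
}

#' Render a spectrogram (or any non-negative matrix) as an RGB image
#'
#' Min-max normalizes per image, log-compresses the normalized values
#' (`log1p(v) / log(2)`, so 0 maps to 0 and the image maximum to 1), and
#' maps each cell through the fixed colour lookup table. Normalizing before
#' the log compression makes the rendering exactly invariant to positive
#' rescaling of the input; a constant matrix maps every pixel to the first
#' table entry.
#'
#' @param spec A `fetmov_spectrogram`, or a non-negative numeric matrix.
#' @return A `fetmov_image`: numeric array `nrow x ncol x 3` in `[0, 1]`.
#' @export
render_rgb <- function(spec) {
  V <- if (inherits(spec, "fetmov_spectrogram")) spec$V else as.matrix(spec)
  if (any(V < 0)) abort("rendered matrices must be non-negative")
  rng <- range(V)
  v <- if (rng[2] > rng[1]) (V - rng[1]) / (rng[2] - rng[1]) else V * 0
  norm <- log1p(v) / log(2)
  idx <- pmin(256L, pmax(1L, as.integer(floor(norm * 255)) + 1L))
  lut <- spectrogram_lut()
  img <- array(0, dim = c(nrow(V), ncol(V), 3L))
  for (ch in 1:3) img[, , ch] <- matrix(lut[idx, ch], nrow(V), ncol(V))
  structure(img, class = c("fetmov_image", "array"))
}

#' Non-negative matrix factorization of a spectrogram
#'
#' Factorizes the magnitude spectrogram `V` (64 x 26) into a basis matrix
#' `W` (64 x rank, spectral shapes) and an abundance matrix `H`
#' (rank x 26, their time activations) with `V ~ W H`, `W, H >= 0`, by
#' multiplicative updates minimizing the Frobenius objective
#' `||V - WH||_F^2` from a seeded non-negative random start. The objective
#' is non-increasing across iterations; iteration stops when the relative
#' objective change falls below `tol` or at `max_iter`.
#'
#' The factors serve as reduced classifier inputs: feeding `W` instead of
#' `V` (algorithm A3) or `H` instead of `V` (A4) shrinks the input far
#' below the full spectrogram.
#'
#' @param spec A `fetmov_spectrogram` or non-negative matrix.
#' @param rank Factorization rank `r`, `1 <= r <= min(dim(V))`.
#' @param seed Integer seed for the random initialization.
#' @param max_iter Maximum multiplicative-update iterations.
#' @param tol Relative objective-change stopping tolerance.
#' @return A `fetmov_nnmf`: list with `W`, `H`, `rank`, `recon_error`
#'   (Frobenius norm of `V - WH`), `n_iter`, and the per-iteration
#'   `objective` trajectory.
#' @export
nnmf_factorize <- function(spec, rank = 5L, seed = 1L, max_iter = 200L,
                           tol = 1e-4) {
  V <- if (inherits(spec, "fetmov_spectrogram")) spec$V else as.matrix(spec)
  if (any(V < 0)) abort("NNMF input must be non-negative")
  if (rank < 1L || rank > min(dim(V))) {
    abort(sprintf("rank must lie in [1, %d]", min(dim(V))))
  }
  eps <- 1e-12
  with_seed(seed, {
    W <- matrix(runif(nrow(V) * rank, 0.1, 1), nrow(V), rank)
    H <- matrix(runif(rank * ncol(V), 0.1, 1), rank, ncol(V))
    obj <- numeric(max_iter)
    prev <- sum((V - W %*% H)^2)
    n_iter <- 0L
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
      cur <- sum((V - W %*% H)^2)
      obj[it] <- cur
      n_iter <- it
      if (prev > 0 && abs(prev - cur) / prev < tol) break
      prev <- cur
    }
    structure(
      list(W = W, H = H, rank = as.integer(rank),
           recon_error = sqrt(sum((V - W %*% H)^2)),
           n_iter = n_iter, objective = obj[seq_len(n_iter)]),
      class = "fetmov_nnmf"
    )
  })
}

#' @export
print.fetmov_nnmf <- function(x, ...) {
  cat(sprintf("<fetmov_nnmf> rank %d, %d iterations, recon error %.4g\n",
              x$rank, x$n_iter, x$recon_error))
  invisible(x)
}

#' @rdname tidy.fetmov_eval
#' @method tidy fetmov_nnmf
#' @export
tidy.fetmov_nnmf <- function(x, ...) {
  tibble(iteration = seq_len(x$n_iter), objective = x$objective)
}

#' @rdname tidy.fetmov_eval
#' @method glance fetmov_nnmf
#' @export
glance.fetmov_nnmf <- function(x, ...) {
  tibble(rank = x$rank, n_iter = x$n_iter, recon_error = x$recon_error)
}

#' @export
as_tibble.fetmov_spectrogram <- function(x, ...) {
  tibble(
    freq_hz = rep(x$freq_hz, times = ncol(x$V)),
    frame = rep(seq_len(ncol(x$V)), each = nrow(x$V)),
    magnitude = as.vector(x$V)
  )
}

#' Plot a magnitude spectrogram
#'
#' @param object A `fetmov_spectrogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fetmov_spectrogram
#' @export
autoplot.fetmov_spectrogram <- function(object, ...) {
  as_tibble(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$frame, .data$freq_hz,
                                 fill = log1p(.data$magnitude))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "log(1+|V|)") +
    ggplot2::labs(x = "frame", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}
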