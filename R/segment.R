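#' Locate the signal peak behind a button annotation
#'
#' Mothers press the button a few seconds after the event they felt, so the
#' annotated instant is searched backwards for the peak: the argmax of
#' `|z|` over `[press_idx - search_back_s * fs, press_idx]`. Ties are broken
#' towards the latest index (the sample closest to the press). On a
#' perfectly flat window the press index itself is returned, with a warning.
#'
#' @param trace A `fetmov_trace`.
#' @param press_idx 1-based sample index of the button press.
#' @param search_back_s How far back (seconds) to search; default 5 s.
#' @return 1-based index of the located peak.
#' @export
locate_annotated_peak <- function(trace, press_idx, search_back_s = 5) {
  stopifnot(inherits(trace, "fetmov_trace"))
  n <- length(trace$z)
  press_idx <- as.integer(press_idx)
  if (press_idx < 1L || press_idx > n) {
    abort("press index lies outside the trace")
  }
  lo <- max(1L, press_idx - as.integer(round(search_back_s * trace$fs)))
  win <- abs(trace$z[lo:press_idx])
  m <- max(win)
  if (m == 0) {
    warn("flat search window: falling back to the press index")
    return(press_idx)
  }
  # latest index attaining the maximum
  lo + max(which(win == m)) - 1L
}

#' Extract a 200-sample peak-centred realization
#'
#' A realization is the fixed-width analysis unit: 200 samples of the
#' (filtered) Z axis with the peak placed at the window median, position
#' 101 of 200 (0-based index 100), i.e. the window spans
#' `peak_idx - 100 .. peak_idx + 99`. Peaks too close to the trace edge
#' cannot yield a full window and raise a boundary error; callers drop
#' such peaks.
#'
#' @param trace A `fetmov_trace`.
#' @param peak_idx 1-based peak index; needs `peak_idx >= 101` and
#'   `peak_idx <= length(trace) - 99`.
#' @param label One of `"fetal"`, `"laugh"`, `"respiratory"`,
#'   `"unlabeled"`.
#' @return One-row tibble with `origin_idx`, `label`, and a `samples`
#'   list-column holding the 200 AMU values.
#' @export
extract_window <- function(trace, peak_idx, label = "unlabeled") {
  stopifnot(inherits(trace, "fetmov_trace"))
  label <- match.arg(label, c(fm_classes(), "unlabeled"))
  n <- length(trace$z)
  peak_idx <- as.integer(peak_idx)
  if (peak_idx < 101L || peak_idx > n - 99L) {
    abort("peak too close to the trace edge for a 200-sample window",
          class = "fetmov_boundary_error")
  }
  tibble(
    origin_idx = peak_idx,
    label = factor(label, levels = c(fm_classes(), "unlabeled")),
    samples = list(trace$z[(peak_idx - 100L):(peak_idx + 99L)])
  )
}

realization_window_width <- 200L
realization_peak_pos <- 101L  # 1-based; 0-based 100

#' Detect candidate event peaks by amplitude threshold
#'
#' Application-mode segmentation: find local maxima of `|z|` at or above a
#' threshold, then enforce a minimum separation, keeping the larger peak
#' whenever two candidates conflict. The default threshold adapts to the
#' session: `median(|z|) + 6 * MAD(|z|)`, since the AMU scale is
#' uncalibrated and varies between subjects.
#'
#' @param trace A `fetmov_trace`.
#' @param threshold Absolute AMU threshold, or `NULL` for the adaptive
#'   default.
#' @param min_separation Minimum distance between returned peaks in
#'   samples; the default 200 keeps application windows non-overlapping.
#' @return Sorted integer vector of peak indices (possibly empty).
#' @export
detect_candidate_peaks <- function(trace, threshold = NULL,
                                   min_separation = 200L) {
  stopifnot(inherits(trace, "fetmov_trace"))
  if (min_separation < 1L) abort("min_separation must be >= 1")
  a <- abs(trace$z)
  if (is.null(threshold)) threshold <- adaptive_threshold(trace)
  n <- length(a)
  if (n < 3L) return(integer())
  is_peak <- a >= threshold &
    a >= c(-Inf, a[-n]) & a > c(a[-1], -Inf)
  cand <- which(is_peak)
  if (!length(cand)) return(integer())
  # larger-|z|-wins greedy suppression
  ord <- cand[order(a[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_separation)) {
      kept <- c(kept, i)
    }
  }
  sort(kept)
}

#' Adaptive amplitude threshold for a trace
#'
#' `median(|z|) + k * MAD(|z|)` (MAD with the usual normal-consistency
#' scaling), robust to the sparse, large event bursts it is meant to catch.
#' The default `k = 8` puts the threshold at about 5 standard deviations of
#' a Gaussian noise floor -- above the expected maximum
#' (`sigma * sqrt(2 log n)`, about 4.9 sigma for a 20-minute session at
#' 280 samples/s) so that event-free sessions yield no candidates, yet far
#' below the default synthetic kick amplitude (20 sigma).
#'
#' @param trace A `fetmov_trace`.
#' @param k MAD multiplier.
#' @return Threshold in AMU.
#' @export
adaptive_threshold <- function(trace, k = 8) {
  a <- abs(trace$z)
  median(a) + k * mad(a)
}

#' Build a labelled training set from annotated sessions
#'
#' Training-mode segmentation. Fetal-movement windows come from button-1
#' presses and laugh windows from button-2 presses, each resolved to the
#' preceding peak with [locate_annotated_peak()] and cut with
#' [extract_window()]; peaks too near an edge are dropped. Respiratory
#' windows are sampled (seeded, uniform) from quiet stretches at least 2 s
#' away from any press-derived window; these are background windows, not
#' peak-centred. When a session lacks enough quiet room, fewer respiratory
#' windows are returned, with a warning.
#'
#' @param traces List of `fetmov_trace` objects (filtered or raw, as the
#'   algorithm variant dictates).
#' @param sessions List of the matching [fm_session()] objects (source of
#'   the button annotations and subject ids).
#' @param search_back_s Peak search window, seconds (default 5).
#' @param n_respiratory_per_session Quiet windows to sample per session
#'   (scalar, or one value per session).
#' @param seed Integer seed for the respiratory sampling.
#' @param session_ids Optional character ids, one per session.
#' @return A tibble of realizations (`subject_id`, `session_id`,
#'   `origin_idx`, `label`, `samples` list-column) with class
#'   `fetmov_realizations`.
#' @export
build_training_set <- function(traces, sessions, search_back_s = 5,
                               n_respiratory_per_session = 5L, seed = 1L,
                               session_ids = NULL) {
  if (!length(traces)) abort("no sessions given")
  if (length(traces) != length(sessions)) {
    abort("traces and sessions must match one-to-one")
  }
  session_ids <- session_ids %||% sprintf("session%02d", seq_along(traces))
  n_resp <- rep_len(as.integer(n_respiratory_per_session), length(traces))
  out <- vector("list", length(traces))
  for (k in seq_along(traces)) {
    tr <- traces[[k]]
    ses <- sessions[[k]]
    rows <- list()
    occupied <- integer(0)
    for (cls in c("fetal", "laugh")) {
      presses <- if (cls == "fetal") ses$btn1_idx else ses$btn2_idx
      for (p in presses) {
        pk <- locate_annotated_peak(tr, p, search_back_s)
        w <- tryCatch(extract_window(tr, pk, label = cls),
                      fetmov_boundary_error = function(e) NULL)
        if (is.null(w)) next
        rows[[length(rows) + 1L]] <- w
        occupied <- c(occupied, pk)
      }
    }
    qc <- quiet_centres(length(tr$z), occupied, tr$fs, n_resp[k],
                        child_seed(seed, k))
    if (length(qc) < n_resp[k]) {
      warn(sprintf("%s: only %d of %d respiratory windows available",
                   session_ids[k], length(qc), n_resp[k]))
    }
    for (cidx in qc) {
      rows[[length(rows) + 1L]] <- extract_window(tr, cidx, "respiratory")
    }
    if (length(rows)) {
      tab <- dplyr::bind_rows(rows)
      tab$subject_id <- ses$meta$subject_id
      tab$session_id <- session_ids[k]
      out[[k]] <- tab
    }
  }
  res <- dplyr::bind_rows(out)
  res <- res[, c("subject_id", "session_id", "origin_idx", "label", "samples")]
  class(res) <- c("fetmov_realizations", class(res))
  res
}

# Seeded uniform draw of n window centres from samples at least 2 s clear of
# every occupied (press-derived) window and far enough from the edges.
quiet_centres <- function(n_samples, occupied, fs, n, seed) {
  if (n < 1L) return(integer())
  ok <- rep(TRUE, n_samples)
  ok[seq_len(min(n_samples, 100L))] <- FALSE
  if (n_samples > 99L) ok[(n_samples - 99L):n_samples] <- FALSE
  guard <- as.integer(2 * fs) + 100L
  for (p in occupied) {
    lo <- max(1L, p - guard)
    hi <- min(n_samples, p + guard)
    ok[lo:hi] <- FALSE
  }
  pool <- which(ok)
  if (!length(pool)) return(integer())
  with_seed(seed, {
    picks <- integer(0)
    for (i in seq_len(n)) {
      if (!length(pool)) break
      c0 <- pool[as.integer(ceiling(runif(1) * length(pool)))]
      picks <- c(picks, c0)
      # keep sampled windows disjoint from each other too
      pool <- pool[abs(pool - c0) > 200L]
    }
    sort(picks)
  })
}

#' Tally realization labels
#'
#' @param realizations A `fetmov_realizations` tibble.
#' @return Tibble with one row per class and its count.
#' @export
class_counts <- function(realizations) {
  realizations |>
    dplyr::count(.data$label, name = "n", .drop = FALSE) |>
    dplyr::filter(.data$label != "unlabeled" | .data$n > 0)
}

# Stack the samples list-column into a (200 x n) matrix.
realization_matrix <- function(realizations) {
  vapply(realizations$samples, as.numeric,
         numeric(realization_window_width))
}
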