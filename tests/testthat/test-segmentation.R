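mk_trace <- function(z, fs = 280) {
  structure(list(z = z, fs = fs, filter = NULL, subject_id = "t"),
            class = "fetmov_trace")
}

test_that("locate_annotated_peak finds the peak behind the press", {
  z <- numeric(3000); z[1000] <- 2
  tr <- mk_trace(z)
  expect_equal(locate_annotated_peak(tr, 1500, search_back_s = 5), 1000)

  # flat window falls back to the press index with a warning
  expect_warning(p <- locate_annotated_peak(mk_trace(numeric(3000)), 1500),
                 "flat")
  expect_equal(p, 1500)

  # tie-break towards the latest index, against a brute-force scan
  z2 <- numeric(3000); z2[900] <- 1.5; z2[1100] <- 1.5
  tr2 <- mk_trace(z2)
  expect_equal(locate_annotated_peak(tr2, 1500), 1100)
  win <- abs(z2[100:1500])
  expect_equal(99 + max(which(win == max(win))),
               locate_annotated_peak(tr2, 1500))

  expect_error(locate_annotated_peak(tr, 5000), "outside")
})

test_that("extract_window cuts 200 samples with the peak at the median", {
  # earliest admissible peak (0-based index 100) covers samples 1..200
  z <- numeric(300); z[101] <- 1
  w <- extract_window(mk_trace(z), 101, "fetal")
  expect_length(w$samples[[1]], 200)
  expect_equal(w$samples[[1]], z[1:200])
  expect_error(extract_window(mk_trace(z), 100), "edge")
  expect_error(extract_window(mk_trace(z), 202), "edge")

  # impulse traces: argmax of the window is always position 101 (0-based 100)
  for (pk in seq(101, 1900, by = 123)) {
    zi <- numeric(2000); zi[pk] <- 3
    wi <- extract_window(mk_trace(zi), pk)
    expect_equal(which.max(abs(wi$samples[[1]])), 101)
  }
})

test_that("detect_candidate_peaks applies threshold, locality, separation", {
  expect_identical(detect_candidate_peaks(mk_trace(numeric(500)), 0.5),
                   integer(0))

  # two supra-threshold peaks 50 apart with min_separation 200: larger wins
  z <- numeric(1000); z[400] <- 1; z[450] <- 2
  got <- detect_candidate_peaks(mk_trace(z), 0.5, min_separation = 200)
  expect_identical(got, 450L)

  # brute-force oracle on random spiky traces
  set.seed(6)
  for (rep in 1:5) {
    z <- rnorm(2000) * 0.01
    spikes <- sample(100:1900, 12)
    z[spikes] <- runif(12, 0.5, 2)
    tr <- mk_trace(z)
    got <- detect_candidate_peaks(tr, 0.4, min_separation = 150)
    a <- abs(z)
    locmax <- which(a >= 0.4 &
                      a >= c(-Inf, a[-length(a)]) & a > c(a[-1], -Inf))
    # greedy larger-first acceptance, brute force
    keep <- integer(0)
    for (i in locmax[order(a[locmax], decreasing = TRUE)]) {
      if (!length(keep) || all(abs(keep - i) >= 150)) keep <- c(keep, i)
    }
    expect_identical(got, sort(keep))
    expect_true(all(diff(got) >= 150))
  }
})

test_that("high-SNR kicks are recovered as candidates near truth peaks", {
  # no posture shifts: a high-passed baseline step is itself a transient
  # event and would rightly produce extra candidates
  cfg <- synth_config(duration_s = 200, kick_rate = 3, laugh_rate = 0,
                      drift_step_amp = 0, seed = 31)
  out <- synth_session(cfg)
  flt <- highpass_filter(select_z_axis(out$session))
  cand <- detect_candidate_peaks(flt)
  kicks <- dplyr::filter(out$truth, kind == "kick")
  expect_equal(length(cand), nrow(kicks))
  expect_true(all(vapply(kicks$peak_idx,
                         function(p) min(abs(cand - p)) <= 20, TRUE)))
})

test_that("event-free sessions yield zero candidates", {
  # event-free: no kicks, laughs, or posture shifts; noise + respiration stay
  cfg <- synth_config(duration_s = 600, kick_rate = 0, laugh_rate = 0,
                      drift_step_amp = 0, seed = 13)
  s <- synth_session(cfg)$session
  flt <- highpass_filter(select_z_axis(s))
  expect_identical(detect_candidate_peaks(flt), integer(0))
})

test_that("build_training_set labels and counts windows correctly", {
  # impulse + press 1 s later: the window centres on the impulse
  z <- numeric(5000); z[2000] <- 2
  tr <- mk_trace(z)
  ses <- fm_session(az = z, btn1_idx = c(2000L + 280L), btn2_idx = 3500L)
  d <- suppressWarnings(
    build_training_set(list(tr), list(ses), n_respiratory_per_session = 3,
                       seed = 2)
  )
  expect_s3_class(d, "fetmov_realizations")
  expect_equal(d$origin_idx[d$label == "fetal"], 2000)
  counts <- table(d$label)
  expect_equal(unname(counts[["fetal"]]), 1)
  expect_equal(unname(counts[["laugh"]]), 1)
  expect_equal(unname(counts[["respiratory"]]), 3)

  # zero presses: only respiratory windows
  ses0 <- fm_session(az = rnorm(5000))
  d0 <- build_training_set(list(mk_trace(ses0$az)), list(ses0),
                           n_respiratory_per_session = 4, seed = 3)
  expect_true(all(d0$label == "respiratory"))
  expect_equal(nrow(d0), 4)
})

test_that("training-mode segmentation recovers truth peaks on the corpus", {
  corpus <- test_corpus()
  n_ok <- 0L; n_tot <- 0L
  for (k in seq_len(nrow(corpus$sessions))) {
    ses <- corpus$sessions$session[[k]]
    truth <- corpus$sessions$truth[[k]]
    flt <- highpass_filter(select_z_axis(ses))
    kicks <- dplyr::filter(truth, kind == "kick")
    for (i in seq_len(nrow(kicks))) {
      pk <- locate_annotated_peak(flt, kicks$btn_idx[i], search_back_s = 5)
      n_tot <- n_tot + 1L
      if (abs(pk - kicks$peak_idx[i]) <= 20) n_ok <- n_ok + 1L
    }
  }
  expect_gte(n_ok / n_tot, 0.95)

  # every emitted realization has exactly 200 samples; press-derived ones
  # peak at position 101
  d <- suppressWarnings(build_training_set(
    lapply(corpus$sessions$session,
           function(s) highpass_filter(select_z_axis(s))),
    corpus$sessions$session,
    n_respiratory_per_session = corpus$n_respiratory_per_session, seed = 4,
    session_ids = corpus$sessions$session_id
  ))
  expect_true(all(lengths(d$samples) == 200))
  # kick windows peak at the median by construction; a laugh can keep
  # rising after the press, putting its true maximum beyond the backward
  # annotation search, so the guarantee is asserted for kicks
  argmaxes <- vapply(d$samples[d$label == "fetal"],
                     function(s) which.max(abs(s)), 1L)
  expect_true(all(argmaxes == 101))
})
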