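#' Configuration for the synthetic-session simulator
#'
#' The simulator emulates the signal phenomenology the pipeline assumes on
#' the maternal abdomen: Z-axis-dominant kick bursts, maternal laugh
#' artifacts that look deceptively like kicks in the time domain, a slow
#' respiratory sinusoid, step-wise baseline drift from maternal posture
#' shifts, wideband sensor noise, and button annotations that lag the true
#' events by a few seconds (the mother's reaction delay).
#'
#' Event counts per session are deterministic, `round(rate * minutes)`, so
#' that a configured class mix is realized exactly in expectation-free form;
#' event placement, morphology, and amplitudes are random under `seed`.
#'
#' @param fs Sampling rate, samples/s.
#' @param duration_s Session length in seconds.
#' @param kick_rate,laugh_rate Events per minute.
#' @param kick_amp,laugh_amp Peak event amplitudes in AMU.
#' @param resp_freq Respiration frequency in Hz (physiological range is
#'   roughly 0.2-0.4 Hz).
#' @param resp_amp Respiration amplitude in AMU.
#' @param drift_step_amp Standard deviation of baseline step sizes in AMU
#'   (steps occur at exponentially distributed intervals, mean 20 s).
#' @param noise_sigma Sensor noise standard deviation in AMU.
#' @param btn_lag_range_s Two-element range (lo, hi) in seconds; each button
#'   press lags its event onset by `Uniform(lo, hi)`.
#' @param seed Integer seed; the whole session is a deterministic function
#'   of the config including the seed.
#' @return A `fetmov_synth_config` list.
#' @export
synth_config <- function(fs = 280, duration_s = 480,
                         kick_rate = 3, laugh_rate = 0.8,
                         kick_amp = 1.0, laugh_amp = 0.8,
                         resp_freq = 0.3, resp_amp = 0.3,
                         drift_step_amp = 0.5, noise_sigma = 0.05,
                         btn_lag_range_s = c(0.5, 5), seed = 1L) {
  assert_scalar_num(fs, "fs", lo = 1e-9)
  assert_scalar_num(duration_s, "duration_s", lo = 1)
  for (nm in c("kick_rate", "laugh_rate", "kick_amp", "laugh_amp",
               "resp_amp", "drift_step_amp", "noise_sigma")) {
    assert_scalar_num(get(nm), nm, lo = 0)
  }
  assert_scalar_num(resp_freq, "resp_freq", lo = 1e-12, hi = fs / 2 - 1e-12)
  if (length(btn_lag_range_s) != 2L || btn_lag_range_s[1] > btn_lag_range_s[2] ||
      any(btn_lag_range_s < 0)) {
    abort("btn_lag_range_s must be (lo, hi) with 0 <= lo <= hi")
  }
  structure(
    list(fs = fs, duration_s = duration_s, kick_rate = kick_rate,
         laugh_rate = laugh_rate, kick_amp = kick_amp, laugh_amp = laugh_amp,
         resp_freq = resp_freq, resp_amp = resp_amp,
         drift_step_amp = drift_step_amp, noise_sigma = noise_sigma,
         btn_lag_range_s = as.numeric(btn_lag_range_s),
         seed = as.integer(seed)),
    class = "fetmov_synth_config"
  )
}

#' Synthesize one event waveform
#'
#' Kicks are modelled as exponentially damped oscillations: a carrier drawn
#' uniformly from 5-20 Hz under an `exp(-t / 0.1 s)` envelope, total length
#' 0.3-0.7 s. Laughs are amplitude-modulated oscillation trains: a carrier
#' (6-14 Hz) modulated by a raised-cosine envelope at 4-6 Hz, lasting
#' 1.5-4 s, so that in a short window a laugh sustains where a kick decays.
#' The waveform is scaled so its peak absolute value equals `amplitude`.
#'
#' @param kind `"kick"` or `"laugh"`.
#' @param duration_s Event duration in seconds.
#' @param amplitude Peak absolute amplitude in AMU.
#' @param fs Sampling rate, samples/s.
#' @param seed Integer seed fixing the carrier, envelope and phase draws.
#' @return Numeric waveform of `round(duration_s * fs)` samples.
#' @export
#' @examples
#' w <- synth_event_waveform("kick", 0.5, 1, fs = 280, seed = 7)
#' max(abs(w))  # exactly 1
synth_event_waveform <- function(kind, duration_s, amplitude, fs = 280,
                                 seed = 1L) {
  if (!is.character(kind) || length(kind) != 1L ||
      !kind %in% c("kick", "laugh")) {
    abort("kind must be \"kick\" or \"laugh\"")
  }
  assert_scalar_num(duration_s, "duration_s", lo = 1e-9)
  assert_scalar_num(amplitude, "amplitude", lo = 0)
  n <- max(1L, as.integer(round(duration_s * fs)))
  t <- (seq_len(n) - 1L) / fs
  with_seed(seed, {
    if (kind == "kick") {
      f <- runif(1, 5, 20)
      phi <- runif(1, 0, 2 * pi)
      w <- exp(-t / 0.1) * sin(2 * pi * f * t + phi)
    } else {
      fc <- runif(1, 6, 14)
      fe <- runif(1, 4, 6)
      phi <- runif(1, 0, 2 * pi)
      w <- 0.5 * (1 - cos(2 * pi * fe * t)) * sin(2 * pi * fc * t + phi)
    }
    m <- max(abs(w))
    if (m > 0) w <- w / m
    w * amplitude
  })
}

#' Generate one synthetic session with ground truth
#'
#' The Z axis is the sum of sensor noise, the respiratory sinusoid,
#' piecewise-constant baseline drift, and the superposed event waveforms;
#' X and Y are attenuated copies (factor 0.2) of the event/respiration
#' content plus independent noise, reproducing the Z-dominance that
#' motivates single-axis analysis. Each kick gets a button-1 press and each
#' laugh a button-2 press, lagged by `Uniform(btn_lag_range_s)`.
#'
#' @param config A [synth_config()].
#' @param meta A [session_meta()] attached to the generated session.
#' @return A list with elements `session` (a [fm_session()]), and `truth`
#'   (tibble: `kind`, `onset_idx`, `peak_idx`, `duration_s`, `amplitude`,
#'   `btn_idx`; indices 1-based, sorted by onset).
#' @export
synth_session <- function(config, meta = session_meta()) {
  stopifnot(inherits(config, "fetmov_synth_config"))
  fs <- config$fs
  n <- as.integer(round(config$duration_s * fs))
  t <- (seq_len(n) - 1L) / fs

  n_kick <- as.integer(round(config$kick_rate * config$duration_s / 60))
  n_laugh <- as.integer(round(config$laugh_rate * config$duration_s / 60))

  with_seed(config$seed, {
    # deterministic-phase respiration so the zero-amplitude invariant holds
    resp <- config$resp_amp * sin(2 * pi * config$resp_freq * t)

    drift <- numeric(n)
    if (config$drift_step_amp > 0) {
      pos <- 0
      level <- 0
      repeat {
        pos <- pos + stats::rexp(1, rate = 1 / 20)
        i0 <- as.integer(ceiling(pos * fs))
        if (i0 > n) break
        level <- level + rnorm(1, 0, config$drift_step_amp)
        drift[i0:n] <- level
      }
    }

    noise_z <- if (config$noise_sigma > 0) rnorm(n, 0, config$noise_sigma) else numeric(n)
    noise_x <- if (config$noise_sigma > 0) rnorm(n, 0, config$noise_sigma) else numeric(n)
    noise_y <- if (config$noise_sigma > 0) rnorm(n, 0, config$noise_sigma) else numeric(n)

    events <- place_events(n_kick, n_laugh, config, n)
    ev_sig <- numeric(n)
    truth <- vector("list", nrow(events))
    if (nrow(events)) {
      for (k in seq_len(nrow(events))) {
        ev <- events[k, ]
        w <- synth_event_waveform(ev$kind, ev$duration_s, ev$amplitude,
                                  fs = fs, seed = child_seed(config$seed, k))
        idx <- ev$onset_idx + seq_along(w) - 1L
        keep <- idx <= n
        ev_sig[idx[keep]] <- ev_sig[idx[keep]] + w[keep]
        peak_idx <- idx[keep][which.max(abs(w[keep]))]
        lag <- runif(1, config$btn_lag_range_s[1], config$btn_lag_range_s[2])
        truth[[k]] <- tibble(
          kind = ev$kind, onset_idx = ev$onset_idx, peak_idx = peak_idx,
          duration_s = ev$duration_s, amplitude = ev$amplitude,
          btn_idx = min(n, ev$onset_idx + as.integer(round(lag * fs)))
        )
      }
    }
    truth <- if (length(truth)) dplyr::arrange(dplyr::bind_rows(truth), .data$onset_idx)
             else tibble(kind = character(), onset_idx = integer(),
                         peak_idx = integer(), duration_s = numeric(),
                         amplitude = numeric(), btn_idx = integer())

    z <- noise_z + resp + drift + ev_sig
    x <- 0.2 * (resp + ev_sig) + noise_x
    y <- 0.2 * (resp + ev_sig) + noise_y

    btn1 <- sort(unique(truth$btn_idx[truth$kind == "kick"]))
    btn2 <- sort(unique(truth$btn_idx[truth$kind == "laugh"]))

    list(
      session = fm_session(az = z, ax = x, ay = y, fs = fs,
                           btn1_idx = btn1, btn2_idx = btn2, meta = meta),
      truth = truth
    )
  })
}

# Draw non-overlapping event onsets, uniform over the feasible arrangements.
# Events keep at least 6 s clearance -- more than the 5 s annotation
# vicinity, so a press's backward peak search never straddles two events.
# Placement is constructive (stick breaking over the slack time), so it
# fails only when the events genuinely cannot fit.
place_events <- function(n_kick, n_laugh, config, n) {
  fs <- config$fs
  kinds <- c(rep("kick", n_kick), rep("laugh", n_laugh))
  if (!length(kinds)) {
    return(tibble(kind = character(), onset_idx = integer(),
                  duration_s = numeric(), amplitude = numeric()))
  }
  durs <- ifelse(kinds == "kick", runif(length(kinds), 0.3, 0.7),
                 runif(length(kinds), 1.5, 4))
  amps <- ifelse(kinds == "kick",
                 config$kick_amp * runif(length(kinds), 0.8, 1.2),
                 config$laugh_amp * runif(length(kinds), 0.8, 1.2))
  gap_s <- 6
  lo_s <- 2
  tail_s <- config$btn_lag_range_s[2] + 1  # room for the lagged press
  ord <- sample(length(kinds))             # random event order along time
  span_s <- durs[ord] + gap_s
  avail_s <- n / fs - lo_s - tail_s
  slack <- avail_s - sum(span_s) + gap_s   # no clearance needed after the last
  if (slack < 0) {
    abort("could not place events without collision: session too short")
  }
  u <- sort(runif(length(kinds), 0, slack))
  onset_s <- lo_s + u + cumsum(c(0, head(span_s, -1L)))
  onsets <- integer(length(kinds))
  onsets[ord] <- as.integer(floor(onset_s * fs)) + 1L
  tibble(kind = kinds, onset_idx = onsets, duration_s = durs, amplitude = amps)
}

#' Generate a multi-subject synthetic corpus
#'
#' Each subject receives a mild multiplicative jitter on event amplitudes
#' and rates (a between-subject effect), so that globally trained versus
#' per-subject trained classifiers can be meaningfully compared. The class
#' mix controls the relative frequency of fetal movements, laughs, and the
#' respiratory (quiet background) windows later sampled per session.
#'
#' @param n_subjects Number of subjects.
#' @param sessions_per_subject Sessions recorded per subject.
#' @param class_mix Length-3 positive weights for (fetal, laugh,
#'   respiratory) realization frequencies; only ratios matter.
#' @param base_config A [synth_config()] used as the template; `kick_rate`
#'   anchors the absolute event frequency and the laugh rate and
#'   respiratory-window count are derived from `class_mix`.
#' @param seed Integer seed for the whole corpus.
#' @return A `fetmov_corpus`: list with `sessions` (tibble: `subject_id`,
#'   `session_id`, `gestational_age`, `n_respiratory`, `session`, `truth`),
#'   `n_respiratory_per_session` (the unjittered per-session count),
#'   `class_mix`, and `seed`.
#' @export
synth_dataset <- function(n_subjects = 10, sessions_per_subject = 2,
                          class_mix = c(1022, 276, 1563),
                          base_config = synth_config(), seed = 1L) {
  if (n_subjects < 1) abort("n_subjects must be >= 1")
  if (length(class_mix) != 3L || any(class_mix < 0) || sum(class_mix) <= 0) {
    abort("class_mix must be 3 non-negative weights with a positive sum")
  }
  if (class_mix[1] <= 0) abort("class_mix must give class 1 positive weight")
  stopifnot(inherits(base_config, "fetmov_synth_config"))

  minutes <- base_config$duration_s / 60
  kicks_per_session <- base_config$kick_rate * minutes
  laugh_rate <- base_config$kick_rate * class_mix[2] / class_mix[1]
  n_resp <- as.integer(round(kicks_per_session * class_mix[3] / class_mix[1]))

  rows <- vector("list", n_subjects * sessions_per_subject)
  r <- 0L
  for (s in seq_len(n_subjects)) {
    sseed <- child_seed(seed, s)
    jit <- with_seed(sseed, exp(rnorm(3, 0, if (n_subjects > 1) 0.15 else 0)))
    ga <- with_seed(child_seed(sseed, 999L), runif(1, 27, 41))
    for (j in seq_len(sessions_per_subject)) {
      cfg <- base_config
      cfg$kick_amp <- base_config$kick_amp * jit[1]
      cfg$laugh_amp <- base_config$laugh_amp * jit[2]
      cfg$kick_rate <- base_config$kick_rate * jit[3]
      cfg$laugh_rate <- laugh_rate * jit[3]
      cfg$seed <- child_seed(sseed, j)
      sid <- sprintf("S%02d", s)
      meta <- session_meta(subject_id = sid, gestational_age = round(ga, 1))
      out <- synth_session(cfg, meta = meta)
      # quiet-window count tracks this session's (jittered) kick count so
      # the corpus class mix follows class_mix regardless of subject effects
      n_kick_ses <- as.integer(round(cfg$kick_rate * minutes))
      r <- r + 1L
      rows[[r]] <- tibble(
        subject_id = sid, session_id = sprintf("%s-%02d", sid, j),
        gestational_age = round(ga, 1),
        n_respiratory = as.integer(round(n_kick_ses * class_mix[3] / class_mix[1])),
        session = list(out$session), truth = list(out$truth)
      )
    }
  }
  structure(
    list(sessions = dplyr::bind_rows(rows),
         n_respiratory_per_session = n_resp,
         class_mix = class_mix / sum(class_mix), seed = as.integer(seed)),
    class = "fetmov_corpus"
  )
}

#' @export
print.fetmov_corpus <- function(x, ...) {
  cat(sprintf(
    "<fetmov_corpus> %d sessions, %d subjects, %d quiet windows/session\n",
    nrow(x$sessions), dplyr::n_distinct(x$sessions$subject_id),
    x$n_respiratory_per_session
  ))
  invisible(x)
}
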