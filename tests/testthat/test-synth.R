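test_that("event waveforms scale, are deterministic, and energy is quadratic", {
  z <- synth_event_waveform("kick", 0.5, 0, seed = 3)
  expect_true(all(z == 0))

  w1 <- synth_event_waveform("kick", 0.5, 1.3, seed = 3)
  w2 <- synth_event_waveform("kick", 0.5, 1.3, seed = 3)
  expect_identical(w1, w2)
  expect_equal(max(abs(w1)), 1.3)

  # doubling the amplitude quadruples the energy (sum-of-squares oracle)
  wa <- synth_event_waveform("laugh", 2, 1, seed = 9)
  wb <- synth_event_waveform("laugh", 2, 2, seed = 9)
  expect_equal(sum(wb^2) / sum(wa^2), 4)

  expect_error(synth_event_waveform("cough", 1, 1), "kick")
})

test_that("an event-free noiseless session is the pure respiration sinusoid", {
  cfg <- synth_config(duration_s = 30, kick_rate = 0, laugh_rate = 0,
                      noise_sigma = 0, drift_step_amp = 0,
                      resp_amp = 1, resp_freq = 0.3, seed = 5)
  out <- synth_session(cfg)
  t <- (seq_along(out$session$az) - 1) / cfg$fs
  expect_lt(max(abs(out$session$az - sin(2 * pi * 0.3 * t))), 1e-9)
  # period 280 / 0.3 ~ 933 samples: count zero crossings
  expect_equal(nrow(out$truth), 0)
})

test_that("sessions are seed-deterministic with truth/button correspondence", {
  cfg <- synth_config(duration_s = 600, kick_rate = 3, seed = 77)
  a <- synth_session(cfg)
  b <- synth_session(cfg)
  expect_identical(a$session$az, b$session$az)
  expect_identical(a$truth, b$truth)

  # 3/min over 10 min -> 30 kicks, each with one button press in lag range
  kicks <- dplyr::filter(a$truth, kind == "kick")
  expect_equal(nrow(kicks), 30)
  expect_setequal(a$session$btn1_idx, kicks$btn_idx)
  lag_s <- (kicks$btn_idx - kicks$onset_idx) / cfg$fs
  expect_true(all(lag_s >= cfg$btn_lag_range_s[1] - 1e-9))
  expect_true(all(lag_s <= cfg$btn_lag_range_s[2] + 1e-9))

  # laughs map to button 2 the same way
  laughs <- dplyr::filter(a$truth, kind == "laugh")
  expect_setequal(a$session$btn2_idx, laughs$btn_idx)
})

test_that("Z-axis variance dominates X and Y at default settings", {
  s <- synth_session(synth_config(duration_s = 120, seed = 2))$session
  expect_gt(stats::var(s$az), stats::var(s$ax))
  expect_gt(stats::var(s$az), stats::var(s$ay))
})

test_that("corpus class mix tracks the configured ratios", {
  # sessions long enough that per-session integer rounding of event counts
  # (the only source of mix error; subject jitter scales all classes alike)
  # stays well inside the band
  corpus <- synth_dataset(n_subjects = 6, sessions_per_subject = 2,
                          class_mix = c(1022, 276, 1563),
                          base_config = synth_config(duration_s = 600),
                          seed = 9)
  truth <- dplyr::bind_rows(corpus$sessions$truth)
  n_kick <- sum(truth$kind == "kick")
  n_laugh <- sum(truth$kind == "laugh")
  n_resp <- sum(corpus$sessions$n_respiratory)
  props <- c(n_kick, n_laugh, n_resp) / (n_kick + n_laugh + n_resp)
  expected <- c(1022, 276, 1563) / 2861
  expect_true(all(abs(props - expected) / expected < 0.05))
})

test_that("corpora are seed-deterministic and subject-jittered", {
  c1 <- synth_dataset(2, 1, base_config = synth_config(duration_s = 60),
                      seed = 3)
  c2 <- synth_dataset(2, 1, base_config = synth_config(duration_s = 60),
                      seed = 3)
  c3 <- synth_dataset(2, 1, base_config = synth_config(duration_s = 60),
                      seed = 4)
  expect_identical(c1$sessions$truth, c2$sessions$truth)
  expect_false(identical(c1$sessions$truth, c3$sessions$truth))

  # single-subject corpora apply no between-subject jitter
  s1 <- synth_dataset(1, 1, base_config = synth_config(duration_s = 60,
                                                       seed = 8), seed = 5)
  base_amp <- synth_config()$kick_amp
  tr <- s1$sessions$truth[[1]]
  kick_amps <- tr$amplitude[tr$kind == "kick"]
  # amplitudes drawn as kick_amp * U(0.8, 1.2): no jitter shifts the band
  expect_true(all(kick_amps >= 0.8 * base_amp & kick_amps <= 1.2 * base_amp))

  expect_error(synth_dataset(2, 1, class_mix = c(0, 0, 0)), "positive")
})
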