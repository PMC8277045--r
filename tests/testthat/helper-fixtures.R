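# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# A small high-SNR multi-subject corpus: 6 subjects x 1 session x 5 min,
# generator defaults minus posture-shift drift (drift transients are
# maternal-movement events; this corpus isolates the kick/laugh/quiet
# contrast). Big enough to train the desk-scale CNN sensibly, small enough
# for module tests.
test_corpus <- function() {
  memo("corpus", synth_dataset(
    n_subjects = 6, sessions_per_subject = 2,
    base_config = synth_config(duration_s = 300, drift_step_amp = 0,
                               seed = 1), seed = 42
  ))
}

test_config <- function() {
  memo("config", pipeline_config(cnn = cnn_spec_small(epochs = 12L)))
}

# One trained A2 report (with model), shared by classifier/pipeline tests.
test_a2_report <- function() {
  memo("a2_report", suppressWarnings(
    run_algorithm(test_corpus(), algorithm_spec("A2"), test_config(),
                  seed = 7, keep_model = TRUE)
  ))
}

# A well-formed on-disk session-log fixture.
write_tiny_session_file <- function(path,
                                    az = c(0.1, -0.2, 0.3, 0, 0.5),
                                    btn1_at = integer()) {
  n <- length(az)
  btn1 <- integer(n); btn1[btn1_at] <- 1L
  lines <- c(
    "#fs=280", "#subject_id=T01", "#gestational_age=30",
    "i,ax,ay,az,btn1,btn2",
    sprintf("%d,0,0,%g,%d,0", seq_len(n) - 1L, az, btn1)
  )
  writeLines(lines, path)
  path
}

# Independent direct-DFT spectrogram oracle: same geometry as
# stft_magnitude, computed from the DFT definition (no fft()).
stft_oracle <- function(samples, win_len = 126L, hop = 3L, pad_to = 201L) {
  x <- c(samples, numeric(pad_to - length(samples)))
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(win_len) - 1) / (win_len - 1)))
  n_freq <- win_len / 2 + 1
  n_frames <- floor((pad_to - win_len) / hop) + 1
  V <- matrix(0, n_freq, n_frames)
  n0 <- 0:(win_len - 1)
  for (j in seq_len(n_frames)) {
    seg <- x[(1 + hop * (j - 1)):(hop * (j - 1) + win_len)] * w
    for (k in seq_len(n_freq)) {
      V[k, j] <- Mod(sum(seg * exp(-2i * pi * (k - 1) * n0 / win_len)))
    }
  }
  V
}
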