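Package: fetmov
Title: Fetal Movement Recognition from Abdominal Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested signal-processing and classification pipeline for
    wearable fetal-movement monitoring. Reads tri-axial abdominal
    accelerometer session logs, removes maternal respiration and baseline
    wander with a zero-phase high-pass filter, segments the Z-axis trace
    into peak-centred 200-sample realizations, converts each realization
    into a 64x26 short-time Fourier magnitude spectrogram (optionally
    factorized by non-negative matrix factorization into basis and
    abundance matrices), and classifies realizations into fetal movement,
    maternal laugh, and maternal respiratory movement with a small
    convolutional network trained by stochastic gradient descent. Includes
    a synthetic-session simulator with ground truth, four algorithm
    variants differing in filtering and feature choice, and evaluation
    tools (confusion matrices, per-class true/false positive rates,
    multi-method detection agreement tables, gestational-age class
    tabulations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
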