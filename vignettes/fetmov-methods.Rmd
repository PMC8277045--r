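---
title: "Methods: recognizing fetal movements in abdominal accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recognizing fetal movements in abdominal accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fetmov)
```

## The problem

Counting fetal movements is a routine, low-cost way of monitoring fetal
well-being, but the standard instrument — the mother's own perception,
logged hour by hour — is unreliable and burdensome, and ultrasound
confirmation is only available in clinic. A belt-worn tri-axial
accelerometer on the maternal abdomen records movement-related acceleration
transients non-invasively; the task is to decide, for each burst of
activity, whether it is a fetal movement (a kick), a maternal artifact that
looks like one (laughing is the most kick-like and most frequent), or
merely background maternal respiratory movement.

`fetmov` implements that recognition pipeline end to end:

1. **Session I/O** — columnar text logs of tri-axial acceleration at 280
   samples/s in the sensor's uncalibrated unit (AMU), plus two button
   channels (button 1: the mother felt a fetal movement; button 2: she
   moved or laughed herself).
2. **Pre-processing** — select the Z axis (normal to the abdomen, where
   event variance dominates) and high-pass filter it.
3. **Segmentation** — cut 200-sample windows ("realizations") centred on
   signal peaks.
4. **Features** — a 64 x 26 short-time Fourier magnitude spectrogram per
   realization, optionally factorized by non-negative matrix factorization
   (NNMF) into a basis matrix `W` and an abundance matrix `H`.
5. **Classification** — a small convolutional network over the rendered
   feature image, trained with stochastic gradient descent on a stratified
   80/20 split.
6. **Evaluation** — 3 x 3 confusion matrices, one-vs-rest per-class
   TPR/FPR, multi-method detection agreement tables, and gestational-age
   class tabulations.

Four algorithm variants differ only in filtering and feature choice:

| id | filter | feature fed to the CNN |
|----|--------|------------------------|
| A1 | none   | spectrogram `V` (64 x 26) |
| A2 | high-pass | spectrogram `V` |
| A3 | high-pass | NNMF basis `W` (64 x rank) |
| A4 | high-pass | NNMF abundance `H` (rank x 26) |

No clinical recordings are distributed with the package; every stage is
exercised on the bundled synthetic-session simulator, whose role and limits
are described below.

## The synthetic-session simulator

`synth_session()` generates the signal phenomenology the pipeline assumes,
with full ground truth. The Z axis is a sum of

* **sensor noise**: white Gaussian, `noise_sigma` (default 0.05 AMU);
* **respiration**: a deterministic sinusoid at `resp_freq` (default
  0.3 Hz, the physiological 0.2-0.4 Hz band), amplitude 0.3 AMU;
* **baseline drift**: a piecewise-constant random walk (posture shifts) —
  steps of s.d. 0.5 AMU at exponentially distributed intervals (mean 20 s);
* **kicks**: exponentially damped oscillations (carrier drawn 5-20 Hz,
  decay constant 0.1 s, duration 0.3-0.7 s, peak amplitude ~1 AMU);
* **laughs**: amplitude-modulated oscillation trains (carrier 6-14 Hz,
  raised-cosine envelope at 4-6 Hz, duration 1.5-4 s, peak ~0.8 AMU), so
  that inside a 200-sample window a laugh *sustains* where a kick *decays*
  — visually similar in the time domain, separable in time-frequency.

X and Y are attenuated copies (factor 0.2) of the event/respiration content
plus independent noise, reproducing the Z-axis dominance that justifies
single-axis analysis. Each kick gets a button-1 press and each laugh a
button-2 press, lagging the event onset by `Uniform(0.5 s, 5 s)` — the
mother's reaction delay, which is why segmentation searches *backwards*
from a press. Event waveform families and amplitudes are the package's own
minimal parameterization: the source material shows morphologies but does
not parameterize them, and gives no amplitude statistics; the defaults were
chosen once to make the three classes separable-but-confusable and are not
revisited. Event **counts** per session are deterministic
(`round(rate x minutes)`), so a corpus realizes its configured class mix
exactly up to rounding; placement, morphology, amplitudes and annotation
lags are random under the seed. Events are placed with at least 6 s
clearance between them — deliberately more than the 5 s annotation
vicinity, so a button press's backward peak search can never straddle two
events (real kicks at ~3/min are similarly sparse). "Event-free" in the
package's tests means kick/laugh rates *and* posture-shift drift at zero:
a high-passed baseline step is itself a maternal-movement transient, which
the detector is supposed to flag and the classifier to reject. `synth_dataset()` adds a mild lognormal
(s.d. 0.15) per-subject jitter on amplitudes and rates so global-versus-
per-subject training comparisons are meaningful; each session's
respiratory-window quota tracks its own (jittered) kick count, so the
corpus class mix follows the configured ratio regardless of subject
effects. The default class mix 1022:276:1563 follows the clinical
tabulation's class ratio.

Session logs are plain text (`#key=value` header, one CSV row per sample,
0-based sample counter, buttons as per-sample 0/1 flags collapsed to
rising-edge events in memory). Doubles are written as `%.17g` and parsed
with correctly rounded `strtod`, so write -> read -> write round-trips are
byte-identical — fixtures can be diffed.

**What passing tests on this simulator do and do not show.** They show the
pipeline's machinery is correct (filtering, alignment, geometry, training,
evaluation, determinism) and that the qualitative contrasts hold (the
filter reduces class-1 false positives; spectrograms beat factorized
features under global training). They do *not* show clinical performance:
real kicks are biomechanically diverse, real artifacts are richer than one
laugh family, sensor coupling varies, and the clinical corpus was larger
and harder. The headline clinical numbers are not reproducible from
synthetic data and the package does not claim them.

## Pre-processing

Respiration (0.2-0.4 Hz) and posture drift sit far below the 5-20 Hz kick
band, so a high-pass filter separates them cleanly. The default
`filter_spec()` is a 4th-order Butterworth high-pass at 1 Hz, applied
forward-backward (zero phase, so peak positions are not shifted —
segmentation depends on that). The designed response attenuates 0.3 Hz by
more than 80 dB over the two passes and leaves 5 Hz within a fraction of a
percent; `filter_response()` evaluates the designed transfer function
analytically so tests can verify the contract without signals.

Numerical choice: before filtering, the trace is reflect-padded by
`ceil(3 * order * fs / cutoff / 4)` samples (about 3 s at the defaults).
The startup transient of a 1 Hz high-pass at 280 samples/s settles on the
scale of `fs / cutoff` samples, so padding proportional to the filter
*order* alone would leave visible edge transients in short sessions.

## Segmentation

A realization is exactly 200 samples with its peak at the window median
(position 101 of 200, 0-based index 100). Two modes:

* **Training mode** (`build_training_set()`): button-1/button-2 presses are
  resolved to the largest `|z|` within the preceding 5 s
  (`locate_annotated_peak()`, ties towards the latest sample, flat windows
  fall back to the press index with a warning), then windowed. Respiratory
  realizations are quiet-background windows sampled at least 2 s away from
  any press-derived window — deliberately *not* peak-centred, mirroring the
  protocol of taking artifact-free stretches as the background class. The
  per-session respiratory count defaults to the class-mix ratio
  (~1.5 x the kick count).
* **Application mode** (`detect_candidate_peaks()`): an amplitude threshold
  plus local-maximum test, then a minimum-separation rule (default 200
  samples, so windows never overlap) resolved largest-peak-first.

The adaptive threshold is `median(|z|) + 8 * MAD(|z|)`. The multiplier is
derived, not tuned: with MAD in its normal-consistent scaling the threshold
sits near 5.1 standard deviations of a Gaussian noise floor, whereas the
expected maximum of `n` noise samples is `sigma * sqrt(2 log n)` — about
4.9 sigma for a 20-minute session at 280 samples/s. The threshold therefore
clears the noise ceiling (event-free sessions yield zero candidates) while
staying far below the default kick SNR of about 20 sigma. The AMU scale is
uncalibrated, which is why the default is adaptive per session; an absolute
AMU threshold can be supplied instead. Peaks closer than 100 samples to an
edge are dropped rather than padded, keeping the 200-sample invariant
unconditional.

## The spectrogram and its factorization

The classifier input is fixed at 64 x 26. The STFT geometry is the unique
simple configuration reaching that shape from 200 samples with no
resampling: symmetric Hann window of 126 samples, hop 3, zero-padding to
201 samples; a one-sided 126-point FFT gives 64 bins and
`floor((201-126)/3)+1 = 26` frames. Bin `k` (0-based) sits at
`k * fs / 126` Hz, so a 40 Hz tone lands exactly in bin 18.

`nnmf_factorize()` minimizes `||V - WH||_F^2` by the classic multiplicative
updates from a seeded uniform start (entries in [0.1, 1], bounded away from
zero so no factor entry is absorbed at 0 spuriously). The objective is
non-increasing by construction (a 1e-12 additive guard in the denominators
only prevents division by zero); iteration stops on a relative objective
change below `tol` (default 1e-4) or at `max_iter` (200). Rank defaults
to 5: no rank is prescribed by the source material, and 5 keeps the A3/A4
inputs (64 x 5 and 5 x 26) an order of magnitude smaller than `V`, which is
the stated point of factorizing at all. The factorization runs on the
magnitude matrix `V`, not on the rendered image: the non-negativity framing
`V = WH, V, W, H >= 0` is a statement about magnitudes, and factorizing
quantized colour channels would discard that structure.

Rendering (`render_rgb()`): per-image min-max normalization, then log
compression `log1p(v)/log 2`, then a fixed 256-entry colour lookup table
with strictly increasing luminance (so larger magnitudes always render
brighter). Normalizing *before* the log keeps the rendering exactly
invariant to positive rescaling of the spectrogram — the property that
matters, since AMU is uncalibrated. The table is a deterministic function
(linear interpolation of six fixed anchors), so images are bit-stable
across platforms. A3/A4 feed `W`/`H` through the same rendering, giving
three-channel inputs of shape 64 x rank and rank x 26.

## The classifier

`cnn_spec()` encodes the reference architecture: three valid (unpadded)
convolution stages with ReLU — kernels 5x3, 5x2, 5x2 with 60, 50, 40
filters — then a flatten and a single dense softmax head over the three
classes; plain SGD at learning rate 1e-4; no pooling, padding, momentum,
weight decay, or class rebalancing (none are part of the reference
configuration; the natural class imbalance is kept, and the split is
stratified per class at 80/20 with floor rounding on the training side).
The reference's per-layer epoch counts (80/150/300) are read as a single
end-to-end epoch budget (default 300); a greedy layer-wise schedule would
be the alternative reading, and is not implemented.

For inputs smaller than the kernels (the `H` matrix is only `rank` rows
tall), `adapt_kernels()` clips each kernel dimension to the spatial extent
available at its stage; the three-stage structure is preserved.

The conv engine is im2col + BLAS matrix products, with the gather/scatter
inner loops in C++ (two small Rcpp kernels); the backward pass is the exact
adjoint and is verified against numerical gradients in the test suite.
Training is bit-reproducible under a fixed seed: initialization, shuffling,
and every update are deterministic functions of it.

**Desk-scale configuration.** The bundled synthetic corpora are small
(~1,300 realizations) and far easier than clinical data, so the package's
own experiments and tests use `cnn_spec_small()` — 8/6/4 filters, 10
epochs, learning rate 0.01 — rather than the full reference network. The
problem sizes used by the test suite and the acceptance script are: a
10-subject x 2-session corpus (8-minute sessions, ~1,300 realizations) for
the A1/A2 detection contrast, a drift-free 6-subject corpus for
segmentation properties and the shared test classifier, and 2-subject
corpora for determinism checks.

## Evaluation conventions

* **FPR** is one-vs-rest per class: false alarms for class `c` over all
  realizations whose true class is not `c`. This is the only reading under
  which a single "false positive rate" is meaningful for a three-class
  detector, and it is the quantity the application must minimize (a false
  kick masks a true decline in movement).
* Rows with empty denominators are flagged `defined = FALSE` rather than
  propagating NaN.
* **Agreement tables** (`agreement_table()`): device and mother events are
  matched to ground-truth (ultrasound-role) events greedily, closest pair
  first, one-to-one, within a 5 s tolerance (the annotation lag bound);
  percentages are shares of ground-truth events, rounded half-up to two
  decimals. Note that half-up rounding of the three pattern shares can sum
  to slightly above 100 (e.g. 100.01).
* **Gestational-age tabulation** (`class_count_table()`): bands 27-31,
  32-35, 36-40+ weeks, with a totals row computed as column sums.

## Determinism

Everything downstream of a seed is a pure function of (data, config, seed):
the generator, the respiratory-window sampler, the split, NNMF starts, CNN
initialization and shuffling. Seeds for sub-streams are derived from the
master seed with a fixed integer recurrence, and every seeded helper
restores the caller's RNG state. Re-running `run_algorithm()` with the same
corpus, config and seed yields byte-identical report JSON
(`eval_report_json()` serializes no timings or environment state).

## Known limitations

* The synthetic kick/laugh families are minimal two-parameter morphologies;
  they bound what the bundled experiments can say about clinical data.
* AMU is treated as an opaque linear unit throughout; no physical
  calibration is attempted.
* Only fetal limb-movement-like events are modelled; movement sub-types
  (startles, hiccups, breathing movements) are out of scope.
* The greedy agreement matcher is order-independent but not globally
  optimal matching (it is the convention chosen, stated here so the
  percentages are interpretable).
* Training is CPU-only and single-threaded beyond BLAS; the reference
  architecture at 300 epochs is practical only for corpus sizes well above
  what the bundled simulator is meant for.
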