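---
title: "Methods: feature-based myoelectric pattern recognition in emgmpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature-based myoelectric pattern recognition in emgmpr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The decoding problem

Surface EMG electrodes over the forearm record a superposition of motor-unit
action potentials.  Different hand and wrist movements recruit different
muscles, so both the amplitude distribution across electrode channels and
the spectral content of the interference pattern carry information about the
intended movement.  `emgmpr` implements the classical window-based decoding
pipeline: short analysis windows are cut from labelled contractions,
summarised by statistical features, optionally projected to a lower
dimension, and classified into one of 11 movement classes (10 movements plus
rest).

The central modelling assumptions are:

* within one contraction, after the transition periods are removed, the EMG
  is approximately stationary at the 200 ms window scale;
* class information is carried by window-level statistics (amplitude,
  variability, spectral shape, inter-channel structure), not by precise
  temporal alignment;
* windows may be treated as exchangeable samples for cross-validation.  The
  last assumption is optimistic — 50%-overlapping windows are statistically
  dependent — and is discussed under *Limitations*.

# Pre-processing

* **Band-pass** 10–500 Hz Butterworth (`filterConfig()`, order 4), removing
  motion artifact below 10 Hz and out-of-band noise; **notch** at 50 Hz with
  a second-order IIR section, quality factor Q = 30.  Both filters run
  forward–backward, so no phase distortion enters difference-based features;
  the effective magnitude response has twice the nominal order.  The notch
  design and Q are package choices (the customary power-line notch), since
  only the centre frequency is canonical.
* **Contraction trimming**: each schedule interval of length L loses
  `round(0.30 · L / 2)` samples at each end.  Rest intervals are trimmed the
  same way — treating the rest class symmetrically is a package choice.
* **Windowing**: 200 ms windows, 100 ms hop, per schedule entry, so a window
  never straddles a class boundary (label purity).  An entry shorter than
  one window is skipped with a warning.  Sample indices are 0-based and
  intervals half-open, which keeps the trimming and window-count arithmetic
  (`floor((L − N)/step) + 1`) free of off-by-one cases.

# Feature definitions and numerical choices

The 44 features follow their conventional printed definitions; the package
fixes the details those definitions leave open:

* The time-domain *variance* block is the uncentred power `sum(x^2)/(N−1)`,
  exactly as conventionally printed for EMG (which is near zero-mean after
  band-passing).  The Hjorth parameters, by contrast, use mean-subtracted
  sample variances — their traditional definition.  This deliberate
  divergence is documented here because both appear in the same feature set.
* Difference-based sums (waveform length, zero crossings) run over the N−1
  adjacent pairs; `sgn(0) = 0`, so exact zeros never count as crossings.
* The slope-sign-change and Willison-amplitude thresholds default to 0
  (`thresholdConfig()`), both configurable.
* *Peaks* (NP/MPV/MFV) are raw samples strictly greater than the window RMS;
  MFV is the mean of successive differences of the peak values, 0 when there
  are fewer than two peaks.
* The curve-length feature `featFDim(x, k)` sums `|X(ik) − X((i−1)k)|` for
  `i ≤ floor((N−1)/k)` (the largest range reachable with 0-based indexing),
  scaled by `(N−1)/N` and divided by `k`.  Higuchi's dimension is the
  two-point log-log slope between k = 1 and k = 10.  The standalone FDim
  feature column uses k = 10 by default: at k = 1 the curve length is a
  rescaled waveform length, which would duplicate an existing block, whereas
  a coarser time-step makes the block behave as a fractal-scale measure.
* The amplitude histogram uses 9 equally spaced bins between the window
  minimum and maximum (per-window range, last bin right-closed).  Nine bins
  is what makes the full time-domain block set come out at its documented
  133-column dimension (22 scalars × 4 channels + 6 correlations + 3 energy
  ratios + 9 × 4 histogram counts).
* The 75th percentile is nearest-rank on the raw sample values.
* Frequency-domain statistics use the one-sided spectrum of the unpadded FFT
  (5 Hz resolution at 400 samples / 2000 Hz); the spectral waveform length
  and the 10 Hz energy bins use the full two-sided array, which makes the
  energy-bin block 200 values per channel and the full frequency-domain set
  828 columns.  The DC bin is included in the energy bins.
* Median frequency is the smallest frequency at which cumulative power
  reaches half the total (with a 1e-9 relative tolerance so an exact half
  split resolves to the lower bin); peak frequency is the argmax of power
  with near-ties (1e-9 relative) resolved toward the lowest frequency; the
  frequency-ratio denominator treats a high band holding only spectral
  leakage (≤ 1e-12 of total power) as empty.
* Wavelet features use periodization boundary handling, under which a
  400-sample window yields exactly 25 coefficients per level-4 subband and
  both transforms conserve energy to float precision — this makes the
  normalized-log-energy denominator `N/2^j` exact and gives the identity
  NLE = 2·LogRMS.  The DWT block set uses the concatenated level-4
  approximation and detail coefficients; the packet features are computed
  for all 16 level-4 subspaces in frequency order (column names `s01..s16`
  make the order explicit).  Logs are natural logs.  Filters are the
  standard 4th-order Coiflet and 5th-order Symmlet orthonormal banks,
  implemented in-package (no wavelet package ships with this R stack) and
  validated against an independent reference implementation; frozen
  reference coefficients live in the test suite.
* Degenerate windows (constant samples, zero-energy subspaces) return `NaN`
  with a warning wherever a feature is genuinely undefined, and 0 where zero
  is the true limit (waveform length of a constant, for example).

# Dimensionality reduction

PCA standardises every column (z-score; zero-variance columns get scale 1
with a warning) before projection, because the feature blocks differ in
scale by orders of magnitude; it is fitted on training folds only.  The
default of 20 retained components mirrors common practice for these feature
sets.

The sequential selection wrapper makes one forward pass (keep a block only
if accuracy strictly increases) and one backward pass in inverted order
(drop a block if accuracy does not decrease).  The empty-set baseline is
chance (100/C %), so the first informative block always enters; candidate
order is the conventional numbering of the blocks.  The evaluator is
injected, so selection can be driven by any classifier.

# Classifiers

* **LDA**: shared-covariance Gaussian discriminant (`MASS::lda`).
* **KNN**: k = 2 with Euclidean distance; a 1-1 vote tie is broken by the
  nearer neighbour, which makes k = 2 well defined (and equivalent to 1-NN).
* **DT**: binary Gini tree (`rpart`), no depth limit, minimum leaf size 1.
* **MLE**: one full-covariance Gaussian per class, equal priors, argmax
  likelihood; a singular class covariance receives a ridge of
  `1e-6 · trace/d` with a warning.
* **SVM**: RBF kernel (`e1071`), cost ∈ 2^{−5..15} and γ ∈ 2^{−15..3} in
  steps of 2², chosen by an inner 3-fold grid search on the training fold.
* **MLP**: two tanh hidden layers of 16 neurons, softmax output, full-batch
  gradient descent with learning rate 0.1 and momentum 0.1, L2 weight decay
  λ = 1e-3 and early stopping on a training-loss plateau.  The
  Bayesian-regularisation trainer familiar from other environments is not
  portable, and the single-hidden-layer `nnet` cannot express the 16-16
  topology, so the network is implemented in-package; weight decay plus
  early stopping plays the same overfitting-control role.

KNN, SVM and MLP inputs are z-scored with training-fold statistics
(configurable), since distance- and gradient-based learners are scale
sensitive.  Every stochastic component — fold shuffling, grid-search inner
folds, MLP initialisation — is seed-controlled, so equal seeds reproduce
identical accuracies, confusion matrices and reports (wall-clock timings
necessarily vary).

Evaluation uses stratified random 10-fold cross-validation within each
subject (fold assignment is seeded identically for every subject, so
duplicated subjects yield identical per-subject results).  Because
overlapping windows are near-duplicates, random folds flatter all
classifiers somewhat; this protocol is retained as the conventional one.
Two accuracy statistics are reported and deliberately kept distinct: the
one-vs-rest class-wise accuracy (TN-inclusive, which is high whenever most
windows are not of class *i*) and the mean per-class recall (the diagonal
average of the row-normalised performance matrix, which is what published
performance matrices print under the table).  The bundled published
matrices (`inst/extdata/performance_*.csv`) are consistent with the second
statistic, not the first, which is why both are exposed.

# The synthetic session generator

`generateSession()` emulates a 4-channel, 2000 Hz recording session: every
repetition cycles through the 10 movement classes, each 2 s contraction
followed by 0.6 s of rest, with the rest class scheduled and labelled like
any other.  Each class is band-pass-filtered white Gaussian noise with a
class-specific per-channel RMS gain pattern, multiplied by a per-contraction
jitter factor `(1 + jitter · ε)`, plus a white noise floor.  This
colored-noise-times-envelope model reproduces exactly the statistical
structure the features measure — amplitude distribution across channels,
spectral content, variability — at trivial cost.

It deliberately does **not** model motor-unit recruitment, electrode shift,
skin-impedance drift, fatigue, crosstalk correlation structure, or
power-line interference.  Passing pipeline tests on synthetic sessions
therefore demonstrates the computational correctness and the discriminative
machinery of the pipeline, not performance on physiological recordings.

The `easyPreset()` gives the 10 movement classes distinct gain patterns
(0.2–1.0 mV) and distinct shaping bands (within 20–450 Hz), 5% jitter, a
rest class at 0.05 mV and a noise floor at 10% of the smallest contraction
gain — separable by construction, so a competent pipeline should decode it
almost perfectly.  The `hardPreset()` compresses the gain patterns toward
their common mean, nearly equalises the bands, triples the jitter and
raises the noise floor until accuracies land mid-range (50–85%), providing
a contrastive fixture that is strictly harder than the easy preset.  Both
are fully determined by their seed.

# Problem sizes used by the tests

The test suite and the acceptance script run single-subject sessions of 3
repetitions (480 windows: 39 per movement class, 90 rest), 10-fold
cross-validation, and estimate the post-shuffling chance level as the mean
recall over three independent label shuffles (one for the SVM, whose grid
search dominates the runtime).  Chance for 11 classes is 100/11 ≈ 9.09%;
the macro-averaged recall of any label-independent predictor equals chance
in expectation regardless of class imbalance, which is why mean recall is
the statistic used for the shuffling checks.

# Limitations

* Within-session, within-subject evaluation only; no between-day or
  between-subject generalisation protocols.
* Random stratified folds over overlapping windows leak information between
  train and test folds; results on real data read higher than a
  contraction-blocked protocol would give.
* The timing harness reports elapsed seconds for training and prediction,
  but absolute values are hardware-dependent and only the mechanism is
  tested.
* Native acquisition-format session files are not parsed; recordings enter
  via the documented CSV dialect or multi-channel WAV.
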