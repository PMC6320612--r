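---
title: "Methods: automated clinical scoring of surface EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated clinical scoring of surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(emgscore)
```

## Scope and model

`emgscore` estimates the 0–10 ordinal clinical scores that an EMG expert
assigns to surface-EMG recordings from functional evaluations: *activity
level* and *spasm severity* for static (rest) tests, *activity level* and
*amplitude modulation* for dynamic (movement) tests, and the derived
*laterality of activity* (|right − left| per muscle). Separate models are
fit per test condition, because electrode geometry, posture and task all
change the amplitude statistics between tests.

The pipeline has four stages: filtering, feature extraction, per-score
regression, and evaluation. Every accuracy figure in the package is
computed on out-of-fold estimates from stratified 10-fold cross-validation,
clipped to the [0, 10] scale.

## Filtering

* Band-pass: 8th-order elliptic design, passband edges 20 and 400 Hz,
  0.5 dB passband ripple, 60 dB stopband attenuation. The low edge removes
  motion artifacts, the high edge instrumentation noise; the stated
  frequencies are interpreted as the passband edges of the elliptic design,
  which is the standard reading of "cut-off" for this filter family.
* Envelope: full-wave rectification followed by a 7th-order elliptic
  low-pass at 10 Hz. The relatively high cut-off preserves the fast
  amplitude-modulation components that spasm scoring relies on.

Both filters are applied forward–backward (`signal::filtfilt`). Zero-phase
filtering preserves burst timing, on which burst detection and the
active-interval features depend; the cost is that effective attenuation and
ripple double (in dB), which the filter tests account for. The stated
orders refer to the designed filters. Ripple, attenuation, edges and orders
are arguments of `emg_bandpass()` / `emg_envelope()` rather than constants.

By default the envelope is computed from the **raw** recording. Whether the
rectified signal should instead be the band-passed one is genuinely open;
passing the `emg_filtered` object to `emg_envelope()` selects that variant.
On the synthetic data the two differ negligibly because the generator's
carrier lies inside the passband.

## Features

* `rms()` — root-mean-square amplitude, µV.
* `band_energy()` — power (µV²) in a frequency band, from a periodogram
  averaged over 1 s rectangular windows with 50% overlap. Windows start at
  t = 0 and a trailing partial window is discarded — the simplest
  deterministic alignment. The estimate is a *power* (PSD integral), so
  values are comparable across trials of different durations. With 1 s
  windows the grid step is 1 Hz and a band covers `[f_lo, f_hi)`.
* `detect_bursts()` — envelope RMS in a 1 s window sliding by 0.25 s;
  greedy selection of non-overlapping windows by descending RMS (ties:
  earlier start). This greedy rule is the lexicographic optimum of the
  sorted RMS triple, which is what "the three largest RMS values" denotes;
  it is *not* in general the triple with the largest RMS sum, and the test
  suite's exhaustive oracle is lexicographic for that reason. Fewer than
  three bursts (flat or short signals) are padded with zeros downstream so
  the dynamic feature vector keeps fixed length.
* `active_intervals()` — samples where the envelope exceeds 1.5 × the
  whole-trial envelope RMS. The same single threshold also defines the
  quiet complement used by `quiet_rms()`; introducing a second, lower
  threshold would have no basis in the method. Note an analytic corollary
  used in the tests: for a two-level envelope at 50% duty cycle the
  threshold can *never* fall between the levels (1.5·RMS ≥ high for any
  level ratio), so threshold-separating examples need duty cycles below
  3/8.
* `dominant_rms()` — the mean over active intervals of the per-interval
  RMS of the band-passed signal. The name follows the field's usage
  ("dominant components"); the construction is the amplitude-threshold one
  above, not a spectral one.
* Static feature vector (4): `rms_env`, `rms_filt`, `e_50_100`,
  `e_100_200`. Dynamic feature vector (11): `rms_env`, `p2p`, `rms_quiet`,
  `t_active`, `burst_rms_1..3`, `dom_rms`, `burst_var_1..3`. Per-burst
  envelope variances are kept separate (rather than pooled) so that the
  variance of the largest burst can be ranked on its own in the importance
  analysis.

## Score models

* **Activity proxy (static).** A no-intercept least-squares fit of the
  expert score on the envelope RMS. No intercept, because a silent muscle
  must map to score 0; an intercept variant is available via
  `calibrate_activity_proxy(intercept = TRUE)`. The regression direction
  (score on RMS) makes the fitted coefficient directly usable as a scoring
  gain.
* **Rebalanced linear models.** Ordinal-score data are heavily
  zero-inflated, so the majority class (score 0 for spasm severity; the
  modal class for dynamic scores) is down-sampled without replacement to
  `round(0.10 × n)`, 10 times; one OLS fit per training set; coefficients
  averaged. The 10% fraction is reused for the dynamic models and exposed
  as the `frac` argument. For spasm severity, scores above 5 are too rare
  to constrain a fit, so each fit uses instances with scores 0–5 and the
  averaged model is then applied to all data; predictions above the fitted
  range are handled by the global [0, 10] clipping rule. Standardized
  coefficients (β·sd(x)/sd(y)) are computed per training set on the same
  data and averaged; their 95% CIs are t-based from the averaged OLS
  standard errors, since no other CI construction is implied by the
  procedure.
* **Bagged regression trees (dynamic).** 100 trees grown on bootstrap
  resamples with `rpart` (variance-reduction splits, `minbucket = 10`,
  `cp = 0`, no feature subsampling at splits — pure bagging, not random
  subspaces). Bagging is robust to class imbalance, so no rebalancing is
  applied. Bootstrap masks are stored; `oob_importance()` reports the mean
  increase in out-of-bag squared error when a feature is permuted among a
  tree's out-of-bag samples, averaged over trees. The `n_perm` argument
  (default 4) averages several permutations per tree to reduce the
  Monte-Carlo noise of the estimate; near-zero importances of redundant
  real features and of planted noise features are otherwise
  indistinguishable.
* **Cross-validation.** Folds are stratified by score value (per-class
  round-robin after shuffling): with 60%+ of mass on score 0, unstratified
  folds regularly lose rare classes entirely.

## Evaluation

RMSE and the least-squares slope of estimates on expert scores without an
intercept (perfect agreement = 1), with a t-based 95% CI. Outliers (beyond
1.5 IQR from the quartiles) are flagged in the per-class box-plot summaries
but excluded from whiskers only — never from any metric. Signed error is
defined as estimate − score, and `error_by_score()` summarizes the bias
trend as the slope of error on score: a misspecified linear model on
saturating feature–score relationships shows a clearly negative trend
(overestimation of low scores, underestimation of high scores), the bagged
trees a much smaller one.

## The synthetic generator

`gen_cohort()` produces score-annotated recordings with the statistical
structure the scoring method assumes:

* **Baseline activity** — broadband Gaussian instrumentation noise
  (2 µV RMS) plus a band-limited Gaussian carrier whose RMS is
  `16 µV × activity score`. The linear mapping reflects isometric
  conditions, where EMG amplitude is linearly related to muscle output.
* **Spasms** — biphasic motor-unit action potentials (Gaussian-derivative
  template, σ = 2.5 ms, ≈ 15 ms wide, 500 µV peak) at quasi-regular
  intervals (interval CV 0.12) with rate `0.2 Hz × spasm score`; severity 0
  adds nothing. Their spectrum concentrates near 65 Hz, i.e. in the
  50–100 Hz band the spasm features integrate.
* **Dynamic trials** — a scheduled envelope with three lifting bursts and a
  fourth return-to-upright burst over a quiet inter-burst level,
  multiplying a unit-RMS carrier. Burst peak amplitude follows a concave
  mapping `10 + 140·(score/10)^0.35` µV and the quiet level decays with the
  amplitude-modulation score down to 8% of the peak; a log-normal ±8%
  trial-to-trial gain models day-to-day amplitude variability. The concave
  mappings are deliberate: they make the linear dynamic models visibly
  misspecified, so the bagged trees' advantage and the linear bias trend
  are reproducible properties of the default cohort.
* **Scores** — drawn from zero-inflated tables (60% zeros for spasm
  severity) for static tests and discretized-Gaussian tables (a clear modal
  class) for dynamic tests; right-side scores add a rounded Gaussian
  offset (sd 0.8) to exercise the laterality derivation.

Two calibration decisions deserve explanation. First, the baseline carrier
band is 100–250 Hz while the spasm MUAPs live at 50–100 Hz. This spectral
separation is a stylized version of a real phenomenon — unsynchronized
interference EMG is built from short single-unit potentials with
higher-frequency content, whereas synchronized spasm potentials are wide
and low-frequency — and it is *required* for the generator's design goal
that raw features track their scores monotonically when activity and spasm
scores are drawn independently: with a 30–150 Hz carrier, baseline power
leaking into the 50–100 Hz band (growing quadratically with activity)
swamps the spasm energy, and no amplitude/rate setting satisfies both
monotonicity goals at once. Second, MUAP amplitude versus rate: the spasm
contribution to the *envelope RMS* scales with the square root of spasm
energy however amplitude and rate are traded, so the activity proxy can
only be protected by keeping total spasm energy small in absolute terms —
hence few, large potentials over a quiet floor rather than many small
ones.

What the generator does **not** emulate: electrode-contact artifacts and
mains interference, non-stationarity within a trial, crosstalk between
left/right channels, fatigue-related spectral compression, inter-subject
amplitude scaling, or the rating noise of a human expert (ground-truth
scores are exact by construction). Passing tests therefore demonstrate
that the pipeline recovers scores *when its structural assumptions hold*;
they do not quantify accuracy on clinical recordings.

## Numerical and degenerate-input conventions

* Amplitudes are microvolts and times seconds everywhere; files are
  comma-delimited UTF-8 with a header. Feature/report files render floats
  with 6 significant digits and round-trip at that precision.
* Recordings must cover ≥ 2 s; filters additionally require three settling
  lengths of data. Sampling rates ≤ 800 Hz are rejected by the band-pass
  (400 Hz edge must sit below Nyquist). Up to 1% missing samples are
  linearly interpolated with a warning, more are rejected; non-monotonic
  time axes are rejected.
* Envelope samples are clipped at 0 (an envelope is an amplitude); estimate
  clipping to [0, 10] is applied at prediction time, never during fitting.
* Rebalancing, fold assignment, tree growing and permutation importance are
  deterministic given a seed; identical seeds reproduce training sets,
  ensembles and estimates bit-for-bit.
* Degenerate inputs fail loudly: zero-variance predictors or responses,
  rank-deficient feature matrices, fewer than 3 distinct proxy scores,
  majority-class targets below one sample. A fully active trial yields
  quiet RMS 0 with a warning; a flat envelope yields no active intervals
  (a constant never exceeds 1.5 × its own RMS).

## Problem sizes used in the checks

The package's own accuracy checks run on synthetic cohorts of 400 trials
(800 recordings: both sides) per protocol — large enough that out-of-fold
RMSE and Spearman statistics are stable to well under the tolerances being
asserted, small enough to run in about a minute. Recovery invariants
(Spearman between truth and out-of-fold estimates, forest-versus-linear
comparisons) are asserted at 200 recordings. Monte-Carlo checks of CI
coverage use 2000 replicates of 2000 pairs.

## Known limitations

* The spasm linear model relies on band-power cancellation between the
  50–100 and 100–200 Hz features to remove the baseline contribution; with
  very short trials (few periodogram windows) that cancellation degrades.
* `dominant_rms` follows the amplitude-threshold construction, not a
  spectral definition, despite its name.
* The force/load-cell channel of lifting evaluations is carried through
  manifests but never analyzed, and accelerometer-based range-of-motion
  analysis is out of scope.
* Model transfer across test conditions is unsupported by design; a model
  is only meaningful for the test it was fit on.
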