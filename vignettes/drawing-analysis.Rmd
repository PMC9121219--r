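---
title: "Drawing-process kinematics as a digital biomarker of global cognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drawing-process kinematics as a digital biomarker of global cognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Screening for cognitive impairment in older adults usually relies on
clinician-administered instruments such as the Montreal Cognitive Assessment
(MoCA, scored 0-30, lower = worse). Digitizer tablets make it possible to
record *how* a person draws — not just the finished trace — during a
standard connect-the-targets task (25 alternating numbers and letters, 24
connecting strokes). The kinematics of that drawing process carry
information about global cognition: people with lower MoCA scores tend to
draw with more variable speed, pause more relative to the time they spend
moving, show more variable pen pressure, and hold the pen with less variable
horizontal inclination.

`drawcog` implements this analysis end to end for synthetic data: a
generative model of raw pen-event streams whose kinematics depend on a
latent cognition score, a feature extractor implementing the six standard
drawing features, a covariate-adjusted correlation analysis with
false-discovery-rate correction, and a cross-cohort random-forest estimator
of MoCA with permutation inference and exact Shapley attributions. Because
no raw human drawing data are publicly deposited for this design, the
package's synthetic cohorts serve both as the test bed and as the
demonstration data set.

## Raw data model

A session is a `pen_stream`: a time series sampled at the tablet rate
(180 Hz by default) with position (mm, inside a 252 x 186 mm active area),
pressure (normalized to [0, 1], quantized to 8192 device levels), two pen
inclinations (degrees) and hover distance (mm). On-surface contact is
defined by `pressure > 0`; hover distance is retained for realism but not
used for segmentation, since pressure is the direct contact signal. A
*stroke* is a maximal contiguous on-surface run.

## The six drawing features

For each session the extractor computes:

* **Mean drawing speed** (mm/s): Euclidean displacement over timestamp
  difference for every consecutive on-surface sample pair within a stroke,
  pooled across strokes, with pairs spanning stroke boundaries excluded and
  no smoothing applied. Time steps come from the timestamps themselves, so
  dropped samples are handled correctly.
* **Speed variability**: the coefficient of variation (sample SD, n-1
  denominator, divided by the mean) of those pooled instantaneous speeds.
  CV rather than SD removes the influence of the absolute speed, which is
  already a feature. Pooling per-sample speeds across strokes (rather than
  averaging per-stroke CVs) was a genuinely open choice; pooling treats the
  drawing speed as one time series, which matches how the signal is
  recorded, and is fixed here.
* **Pressure variability**: the raw median absolute deviation (no 1.4826
  consistency constant) of on-surface pressure, robust to the pressure
  spikes that digitizer pens produce.
* **Inclination variabilities**: plain sample SDs of the horizontal and
  vertical inclination over on-surface samples. The angles are treated as
  linear quantities in degrees, not circular ones — appropriate for the
  small excursions a writing grip produces.
* **Pause:drawing duration ratio**: total pause time divided by total
  drawing-motion time. Pauses are of two kinds. *Within-stroke* pauses are
  detected with a greedy anchor scan: from an anchor sample the window
  extends while every sample stays within 0.25 mm of the anchor's position;
  a window lasting strictly more than 100 ms is a pause, and the scan
  restarts after it (otherwise the anchor advances one sample). The circle
  is centered on the anchor sample, a deterministic and oracle-checkable
  reading of "remained inside a 0.25-mm radius". *Between-stroke* pauses
  are the pen-up intervals separating consecutive strokes, with no minimum
  duration. Since dwelling is not drawing motion, within-stroke pause time
  is subtracted from the stroke-duration total in the denominator — another
  open convention fixed and documented here.

The scan is implemented in C++ (it is the only per-sample loop in the
package) and is verified against an O(n^2) brute-force oracle.

## The synthetic-data generator

The generator emulates the study conditions of a two-nation validation
design: a US-like cohort (n = 55; age 83.4 (SD 6.9) years; 71% female;
education 16.3 (2.3) years; MoCA 24.4 (3.2)) and a Japan-like cohort
(n = 37; age 73.3 (4.5); 51% female; education 13.8 (2.0); MoCA 24.4
(2.6)), with participant MoCA scores spanning 16-30. Age and education are
truncated normals (65-100 and 6-25 years); sex is Bernoulli with 1 =
female; MoCA is normal, clipped to range and rounded.

Kinematics hang off the standardized MoCA score \(z\). Each generating
parameter (mean speed, within-stroke speed CV, pressure dispersion, the two
inclination dispersions, and the pause budget) follows a lognormal link

\[ \log(\theta_i) = \log(\theta_0) + b\,z_i + \varepsilon_i, \qquad
   \varepsilon_i \sim N(0, \tau^2), \]

with \(b = \tau r / \sqrt{1 - r^2}\) so that the population correlation
between \(\log \theta\) and \(z\) equals a configured target \(r\). The
default targets reproduce the published correlation pattern of drawing
features with MoCA in older adults: speed CV -0.42, pause ratio -0.49,
pressure MAD -0.34, horizontal-inclination SD +0.33, vertical-inclination
SD +0.17, mean speed 0. The log link keeps dispersions positive and is the
simplest monotone choice that achieves the target sign/magnitude pattern;
\(\tau = 0.25\) gives plausible between-participant heterogeneity
(roughly +/- 25%). A global `strength_scale` multiplies every target
(0 disables all associations, used for null calibration), and an optional
`age_confound` switch makes age directly lower both MoCA and mean speed so
that the difference between plain and covariate-adjusted correlation is
testable.

Sessions themselves are planned and then realized: 25 targets placed
uniformly with a 10-mm margin and rejection-sampled to at least 20 mm
spacing (avoiding degenerate zero-length strokes); straight strokes whose
per-sample step lengths carry multiplicative lognormal noise calibrated so
the realized speed CV equals the planned one; dwell events that hold the
pen exactly stationary; pen-up gaps with zero pressure and a positive
hover arc; pressure and inclinations as AR(1) processes (autocorrelation
0.9 and 0.97) around per-participant baselines with the planned marginal
dispersions. The pause budget is expressed relative to the planned drawing
time (split 18% dwells / 82% pen-up gaps at baseline ratio 0.38), which
decouples the realized pause ratio from the participant's drawing speed.
Defaults give sessions of roughly two minutes at 180 Hz — the duration
scale reported for this task in older adults.

What the generator does *not* emulate: the actual task stimuli and
error-making behavior (wrong-target excursions), tremor spectra, curvature
of real pen trajectories, device placement effects, or any causal structure
beyond the single latent link (plus the optional age confound). Passing
tests therefore demonstrate that the pipeline's statistics and machinery
behave correctly under a faithful covariance structure, not that the
effect sizes would be recovered from real tablets.

One deliberate interaction is worth noting: instantaneous speeds include
near-zero samples during within-stroke dwells (the extractor's contract is
every consecutive on-surface pair). Participants with larger pause budgets
therefore show slightly inflated speed CVs, which mildly strengthens the
negative speed-CV correlation relative to its configured target. The
calibration check allows for this (tolerance +/- 0.15 on each configured
magnitude), and the effect is in the direction real data show anyway —
pausing and speed variability co-occur.

## Statistical analysis

Partial correlations residualize the feature and the MoCA score on an
intercept plus age, sex and education by least squares and correlate the
residuals. The p-value uses \(t = r\sqrt{(n-2-k)/(1-r^2)}\) on \(n-2-k\)
degrees of freedom; the 95% CI uses the Fisher z transform with
covariate-adjusted effective sample size \(n - 3 - k\) (the exact CI
convention of the original software is not documented; this is the common
choice). Benjamini-Hochberg correction is applied within the six-feature
family separately for each analysis subset, mirroring per-data-set
correction. Demographic contrasts use pooled-variance (Student) t tests —
matching single-df reporting for a two-cohort design — and a 1-df
chi-square without continuity correction for sex, the convention that
yields the familiar 3.63 statistic for a 39/55 versus 19/37 split of women.

## The cross-cohort model

The estimator is a random-forest regressor of MoCA on the six features,
trained on one cohort and evaluated on the other. Tuning is an exhaustive
search over 144 combinations (tree depth 2-4; 2, 3, 4 or 6 candidate
features per split; bootstrap sample fraction 1.0, 0.75, 0.5; minimum leaf
size 2-5) with 500 trees each, by 10-fold cross-validation with a seeded,
once-shuffled fold assignment. The selection criterion is pooled
cross-validated squared error (the original choice of CV metric is
unstated; MSE is the natural one for a regression forest), with ties broken
by the first combination in depth-major enumeration order. All remaining
forest parameters are pinned explicitly (bootstrap with replacement,
single-threaded, fixed tree seeds) so behavior is implementation-independent.

Evaluation reports \(R^2 = 1 - SS_{res}/SS_{tot}\) with \(SS_{tot}\) about
the *test-set* mean — the convention under which \(R^2\) and the squared
Pearson correlation can legitimately diverge — plus Pearson r, MAE and
RMSE.

The permutation test permutes the *training* labels, refits with the
already-chosen hyperparameters (re-tuning for each of 1000 permutations is
available behind `retune = TRUE` but is not the default, both for
tractability and because fixing hyperparameters chosen once keeps the test
exact under exchangeability), evaluates on the intact test set, and uses
the add-one p-value estimator \((1 + \#\{stat \ge obs\})/(1 + B)\), which
cannot return zero.

Feature importance uses exact Shapley values: with six features the
\(2^6 = 64\) coalitions are enumerated outright, each valued as the
background-averaged model output with the coalition's features fixed at
the explained sample (interventional expectation). This makes the
additivity axiom hold to machine precision and is preferable to
path-dependent approximations at this dimensionality. By default the test
cohort is explained against the training cohort as background — importance
should describe the model where it is deployed; both are configurable.

## Numerical choices and degenerate inputs

* Streams must have strictly increasing timestamps; feature extraction
  requires at least one stroke with two samples and errors informatively
  otherwise. Truncated sessions are processed as-is.
* Pressure is clipped to [0.05, 0.995] before quantization so on-surface
  samples never quantize to zero pressure.
* A constant training target ties all 144 grid cells; the first cell in
  enumeration order is chosen and predictions are constant.
* A zero-variance test target makes \(R^2\) undefined and is an error; a
  constant predictor yields an undefined Pearson r, reported as `NA` in
  metrics and treated as zero association inside the permutation loop.
* `bh_adjust` validates p-values to (0, 1]; the implementation delegates to
  `p.adjust(method = "BH")` and is property-tested against the direct
  step-up definition.
* All randomness is seed-scoped: library calls never disturb the caller's
  RNG state, and stage seeds are derived deterministically from one master
  seed.

## Problem sizes used by the test suite

The suite verifies oracle equivalence at full precision on small random
sessions, and runs the simulation-heavy calibrations at sizes chosen to
keep the whole suite a matter of minutes on one core: generator calibration
against the configured correlation structure at n = 500 per cohort with
full-length (~2-minute) sessions; cross-cohort signal recovery at
n = 200/200 over 10 seeds with ~30-second sessions (faster nominal drawing,
same 25-target task); permutation-null calibration over 100 repeats at
n = 40/30 with ~13-second sessions, B = 99, and fixed mid-grid
hyperparameters (valid because hyperparameters fixed independently of the
labels preserve exchangeability). These sizes are the package's own
choices; the calibration properties they check are size-stable.

## Limitations

The package analyzes synthetic data only; its empirical claims are about
the correctness and calibration of the machinery, not about clinical
performance. The generative model is a calibration device — a single
latent-factor structure matched to published correlation magnitudes — and
real drawing data will contain structure (nonlinear feature interactions,
task errors, device artifacts, cultural differences between cohorts) that
it does not represent. Headline human-data results (cross-cohort
\(R^2 \approx 0.35\)) are consequently not reproduction targets here.
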