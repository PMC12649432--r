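---
title: "Quiet-eye extraction and attention linkage: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quiet-eye extraction and attention linkage: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quieteye)
```

This vignette documents the scientific and numerical choices behind
`quieteye`: the measurement model for gaze behaviour in a targeting task,
the scoring rules for the two attention instruments, the statistical layer,
and — in most detail — what the synthetic-cohort generator emulates, since
every end-to-end claim the package makes is certified against it.

## 1. The measurement model

### Gaze geometry

Gaze is recorded by head-mounted eye-tracking glasses whose scene camera
(1280 × 960 px; 60° horizontal × 46° vertical field of view) moves with the
head, while the pupil cameras sample gaze at 60 Hz. All coordinates are
*head-fixed scene-camera degrees*, origin at the frame centre, y up. The
pixel-to-degree map is linear (constant degrees per pixel), not
tangent-corrected: at the ≤ 30° eccentricities of this task the
linearization error is far below the 0.5° accuracy of the instrument and
the 1° criterion used for the quiet eye, and the choice is isolated in
`pixels_to_degrees()` should a tangent map ever be needed.

Invalid samples (lost pupil) are *retained* in the trace with `NA`
coordinates. This is deliberate: the tracking ratio that screens trials
needs the total sample count as its denominator.

### Fixation detection (I-DT)

The commercial software used with such trackers detects fixations with an
undisclosed proprietary algorithm. The package instead specifies the
standard dispersion-threshold algorithm (I-DT), which we can state, test
and certify exactly:

* grow a window of consecutive valid samples while
  `max(range(x), range(y)) <= dispersion`;
* emit a maximal window as a fixation when its wall-clock span reaches the
  minimum duration, else slide the window start by one sample.

Defaults: dispersion 1.0° (matching the quiet-eye spatial criterion),
minimum duration 100 ms. Runs of invalid samples are bridged when the gap
between the flanking valid samples is at most 75 ms (roughly a blink of
4 dropped samples at 60 Hz); bridged samples are excluded from the
centroid, but the duration keeps the wall-clock span. Longer gaps
terminate the window. No published gap rule exists for the original
processing chain, so the tolerance is a parameter, and the defaults are
not claimed to reproduce the proprietary detector. Saccades are never
materialized as events — only fixations are analysed.

The compiled scanner is verified, in the test suite, against a brute-force
oracle that recomputes every candidate window's dispersion from scratch,
on 1000 random traces mixing plateaus, drifts, signal loss and dropped
samples.

### Trial screening

A trial is unreliable if its tracking ratio (valid samples / all samples)
falls below 0.85 or its fixation ratio (summed fixation time / trial span)
below 0.60 — thresholds recommended for mobile eye tracking in children.
The fixation-ratio denominator is the full first-to-last-sample span; this
operational choice is configurable because the original is unstated.
Participants with fewer than 5 reliable trials (of 10) are excluded
entirely; the majority-of-trials default is likewise an explicit choice
where the source procedure gives none.

### Synchronization and the pre-throw window

The gaze stream and the external (side-view) kinematic camera are
synchronized by a single optical flash visible to both. One constant
offset per recording is assumed — no drift model; over a session of a few
minutes the drift of consumer clocks is far below the 16.7 ms sample
interval, and the single-flash design gives no way to estimate drift
anyway. The analysis window is the half-open interval `[release − 2000 ms,
release)` on the eye clock. Release anchoring (rather than initiation
anchoring) and the 2000 ms width cover the whole preparatory phase:
movement initiation in throwing typically precedes release by ~600 ms and
preparatory processing begins ~1400 ms before release. The half-open
convention prevents double counting at the boundary.

### Quiet-eye definitions

* **QE fixation**: the last fixation whose centroid lies within 1° of the
  virtual target (the annotated wall position of the ball rebound) and
  whose onset *strictly* precedes movement initiation. A fixation starting
  exactly at initiation is rejected — "before initiation" is read
  literally, and the tie rule is documented here.
* **QE onset**: initiation time minus QE fixation onset; positive values
  mean the fixation leads the movement. Strict precedence makes it
  positive whenever defined.
* **QE duration**: the *full* fixation duration, not truncated at
  initiation. This is the standard quiet-eye convention: the quiet eye
  may — and typically does — extend into the movement itself.
* **Fixation count / total fixation time (TT)**: fixations overlapping the
  window, with durations clipped to it, so TT is bounded by 2000 ms.

Trials without a qualifying QE fixation contribute to the count and TT
means but are missing (not zero) for the QE means: a zero would conflate
"never fixated the target" with "fixated it briefly", which are different
behaviours.

## 2. Attention instruments

**d2-R.** 14 rows × 57 characters (`d`/`p` with 1–4 dashes); the target is
`d` with exactly two dashes; rows 2–13 carry 308 targets and 376
distractors and are the only scored rows; each row is worked for 20 s
(280 s total). Scoring: commissions are marked distractors, omissions are
unmarked targets *within the processed span* of each row (the rightmost
mark, or an explicit end-of-progress record when available — the generator
emits one). `CP = correctly marked targets − commissions`;
`%errors = 100·(commissions + omissions)/processed targets`. The phrase
"processed targets minus commissions" is ambiguous; the package implements
the standard correctly-marked reading and exposes the literal one behind
`cp_literal = TRUE`. Standard scores come from a norm table; since real
d2-R norms are proprietary, the bundled `d2_norms_synthetic.csv` is a
*synthetic surrogate* — a linear raw-to-SS map anchored at mean 100 / SD 10
in the synthetic norm population — and any licensed table in the same CSV
format can be substituted.

**Reaction-time alertness.** Only the 28-trial non-signal set is scored
(tonic alertness). A response is correct when it lands in the 100–1000 ms
window; sub-100 ms responses are treated as anticipations and scored
incorrect — a standard reaction-time hygiene rule the source description
does not state, configurable via `anticipation_ms`. SDRT is the sample SD
(n − 1); CVRT = 100·SDRT/mean RT is computed per participant and only then
averaged — the ratio of cohort means is a different (and larger) number,
which is worth remembering when comparing cohort tables.

## 3. Statistical layer

* Descriptives: type-7 quantiles, adjusted Fisher–Pearson skewness,
  Shapiro–Wilk normality p (via `stats::shapiro.test`).
* Pearson r with `t = r√(n−2)/√(1−r²)`; pairwise-complete deletion for
  single correlations, listwise for multivariate operations (documented,
  since the source is silent).
* Shared variance: R² of each attention score on the four eye variables,
  with the overall F-test. Regression *coefficients* are deliberately not
  reported: the eye variables are strongly intercorrelated and the
  coefficients are unstable, while R² is well defined.
* CCA: computed by the orthogonal route — standardize columns, QR-decompose
  each set, take singular values of `Qx'Qy`. This avoids explicitly
  inverting within-set covariance matrices; the textbook eigen-solution of
  `Sxx⁻¹SxySyy⁻¹Syx` serves as the test oracle (agreement to 1e-8 on 500
  random instances). An ill-conditioned within-set correlation matrix
  (condition number above `max_condition`, default 1e10) raises an error
  advising variable removal rather than returning garbage. Canonical signs
  are arbitrary; each variate is oriented so its largest-magnitude loading
  is positive, so published solutions may differ from ours by a global
  flip per variate.
* Sequential Wilks lambdas `Λ_k = Π_{i>k}(1−ρ_i²)` with a permutation test
  that permutes whole rows of one set (preserving within-set correlation),
  `p_k = (#{Λ*_k ≤ Λ_k} + 1)/(B + 1)`. With B = 999 the test is exact at
  the 5% level under exchangeability; the suite verifies empirical type-I
  error in [0.04, 0.06] over 2000 null replicates.
* Bootstrap double-check of correlations: pairs bootstrap, studentized on
  the variance-stabilized scale — `p = 2·P(T ≤ −|atanh r|/sd(atanh r*))`
  with a t(n−3) reference. The naive percentile rule (share of resampled
  r* beyond zero) was measured to reject ~6.3% of true nulls at n = 57
  because the pairs bootstrap underestimates sd(r) by ~4% at this sample
  size; the studentized variance-stabilized form measured 5.4%, and is the
  package's choice of "nonparametric bootstrap". No multiplicity
  adjustment is applied across the correlation table — cells are reported
  with unadjusted p-values, as is conventional for these descriptive
  matrices.

## 4. The synthetic cohort generator

The generator emulates the study conditions end to end: 57 children aged
9–12, 10 test throws each, 60 Hz gaze, a d2-R sheet with the fixed bundled
stimulus layout, and a 28-trial alertness test.

### Structure

A single standard-normal latent attention factor `A` per participant
drives every cross-domain dependence; each participant-level parameter is
`mean + sd·(±w·A + √(1−w²)·noise)`. Marginal means and SDs default to
values typical of this population: QE onset 474 (227) ms, QE duration
754 (289) ms, TT ≈ 1.5 s, ~4 fixations per window, %errors ≈ 10% raw,
mean RT 357 (54) ms, SDRT 56 (19) ms, ~26.6 correct responses (the cap at
28 produces the characteristic negative skew). Signs follow the emulated
direction of effect: higher `A` means earlier quiet eye, shorter QE
duration, slightly more fixations, fewer d2 errors, faster and steadier
responses, more catches.

A trial's trace (2.5–3.5 s) alternates fixations (gamma-distributed
durations, shape 2, participant-specific mean ≈ 380 ms) with 33–50 ms
saccade gaps and, with probability 0.25, a longer 150–350 ms unstable-gaze
episode; these parameters are plausible at 60 Hz, not claimed
physiological, and were set once to land the window-level fixation count
and TT near the emulated means. Gap samples follow a fast zigzag path
(consecutive-sample displacement > 1°) so no spurious fixation can form —
which also makes noise-free recovery exact. One target-anchored fixation
is planted per trial with onset `initiation − QE-onset draw` (snapped to
the sample grid) and centroid within 0.8° of the annotated target; filler
centroids stay ≥ 2.5° from the target so the quiet-eye selector can only
find the planted fixation. Movement initiation sits ~600 ms before
release. Within-fixation jitter is Gaussian (SD 0.15°); 2% of samples are
invalid by default.

### Planting the cross-domain correlation

`r_target` is defined as the population correlation between the two
*observable* participant-level variables: 10-trial mean QE onset and the
%errors standard score. The observables are attenuated relative to the
latent participant parameters by two noise sources the generator knows
exactly:

1. trial-to-trial QE-onset scatter (SD 150 ms) averaged over 10 trials —
   additionally, the trial draw is truncated below (a quiet-eye onset must
   be positive and feasible inside the trace), which compresses the low
   tail of participant means; the X-side attenuation is therefore obtained
   by numerically integrating the truncated-normal trial mean and variance
   over the latent participant distribution rather than from the plain
   additive-noise reliability;
2. mark-level binomial noise in the d2 error percentage, whose variance
   follows from the sheet composition, the processed span and the
   omission/commission probabilities.

The generator divides `r_target` by the product of the two attenuation
factors to obtain the latent correlation it actually plants, and refuses
configurations that would require a latent correlation above 0.95. Two
small effects are knowingly ignored: detection noise in the QE onset from
occasional invalid samples (~0.3% attenuation) and the truncation of the
error percentage at 0.5% (affects ~2–3% of draws); both are an order of
magnitude below the acceptance tolerance.

### What passing tests do and do not show

The generator's planted structure is a *single* latent factor with
Gaussian noise; real cohorts have heavier tails, trial-order effects,
fatigue, and measurement artefacts (calibration drift, asymmetric signal
loss) that it does not emulate. End-to-end recovery therefore certifies
the pipeline's correctness and calibration under the stated conditions —
it does not certify that any particular real cohort satisfies them.

## 5. Problem sizes and runtime choices

The suite's problem sizes were chosen as the smallest that make the
statistical checks sharp: 1000 random traces for the detector oracle, 500
random instances for the CCA oracle, 2000 null replicates (B = 999) for
the calibration checks, and 200 simulated cohorts for parameter recovery
(the Monte-Carlo SE of the recovered mean correlation is then ~0.008,
comfortably below the ±0.05 recovery tolerance). The acceptance script
reruns the 200-cohort recovery from a user-supplied seed.

## 6. Known limitations

* 60 Hz sampling bounds the temporal precision of QE onset/duration to one
  16.7 ms sample; microsaccades are undetectable at this rate by design.
* The I-DT defaults are not a reconstruction of the proprietary detector;
  quantitative agreement with records processed by commercial software is
  not guaranteed, and the tracking/fixation-ratio definitions are our
  operationalizations of an unstated rule.
* The bundled norm table is synthetic; standard scores from it are
  internally consistent but not comparable to licensed d2-R norms.
* The virtual target is consumed as a per-trial annotation; the package
  does not digitize it from video.
* With 4-vs-6 variable sets at n = 57, canonical correlations are
  estimated with substantial sampling noise; the permutation test is the
  honest inferential guard, and single-cohort loadings should be read
  qualitatively.
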