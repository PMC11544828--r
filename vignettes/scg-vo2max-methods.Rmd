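---
title: "Estimating VO2max from resting seismocardiography: models, simulators and validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating VO2max from resting seismocardiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scgvo2)
```

## The problem

Maximal oxygen uptake (VO2max, mL/min/kg) is the standard index of
cardiorespiratory fitness and a strong predictor of cardiovascular risk and
mortality. Its reference measurement — cardiopulmonary exercise testing
(CPET) to voluntary exhaustion with breath-by-breath gas analysis — is
laborious and unsuitable for many clinical settings. Seismocardiography
(SCG) records the chest-wall vibrations produced by the beating heart with
a sternal accelerometer; because maximal cardiac output dominates VO2max,
features of the resting SCG waveform carry information about fitness and
can drive a *non-exercise* VO2max estimate.

`scgvo2` implements such an estimation pipeline end to end, together with
the method-comparison statistics used to validate one estimator against a
CPET reference, and — because subject-level data from device studies are
not publicly deposited — a synthetic-data module that generates cohorts,
SCG recordings and CPET traces carrying the statistical structure the
downstream analysis assumes. Every stage is therefore testable without any
external download, and the whole study design (two rest recordings before
the CPET, one post-exercise recording, exclusion rules, subgroup analyses)
can be rerun reproducibly from one seed.

## The estimation model

The SCG estimator is a linear regression on anthropometrics and four
SCG-derived measures of the ensemble-average heartbeat:

$$\widehat{VO_2max} = \omega_0 + \omega_1\,\mathrm{Sex} +
\omega_2\,\mathrm{Age} + \omega_3\,\mathrm{Weight} +
\omega_4\,\mathrm{Height} + \omega_5\,\mathrm{RR} +
\omega_6\,\mathrm{Dia_{PtP}} + \omega_7\,\mathrm{Dia_{Morph}} +
\omega_8\,\mathrm{Sys_{Spec}}$$

with sex coded 0 = male / 1 = female, age in years, weight in kg, height in
m, and

* **RR** — mean heartbeat duration (ms): resting heart rate falls with
  fitness;
* **Dia~PtP~** — peak-to-peak amplitude (m/s²) of the diastolic SCG complex
  of the averaged beat, a proxy of diastolic filling;
* **Dia~Morph~** — first-principal-component score of the diastolic-window
  waveform shape;
* **Sys~Spec~** — first-principal-component score of the systolic
  magnitude spectrum, a proxy of contractility-related frequency content.

The coefficients of the commercial device implementing this idea are
proprietary and unpublished. This package therefore *fits* the equation by
ordinary least squares on (synthetic) training data rather than shipping
trained weights; that choice is the minimal faithful reading of the
published linear model form, and the package never claims to reproduce the
device's numbers. `fitScgVo2Model()` refuses rank-deficient designs (naming
the offending column) and records the residual SD and coefficient standard
errors needed for calibration tests.

Two fully specified published benchmarks are implemented exactly:

* FRIENDS non-exercise equation:
  `79.9 − 0.39·age − 13.7·sex − 0.127·weight_lbs` (weight converted from kg
  with factor 2.20462). Because it is linear, its prediction at cohort
  means equals the mean of per-subject predictions — which is why
  cohort-level predictions reported from summary statistics are exactly
  recomputable (`predictFriends(48.2, 0.521, 76.5)` → 32.5 after 1-dp
  rounding).
* ACSM peak-power equation: `10.8·peakPower/weight + 7`, and the Tanaka
  age-predicted maximal heart rate `208 − 0.7·age`.

## Signal processing

A recording is 42 s of single-axis sternal acceleration at 250 Hz (the SCG
band of interest lies well below 50 Hz, so 250 Hz leaves ample margin).
Processing follows the classical ensemble-average approach:

1. **Beat detection** (`detectBeats()`): band-pass 13–45 Hz isolates the
   systolic complex (diastolic energy sits at or below ~10 Hz), the
   analytic (Hilbert) envelope localizes each burst, and peaks separated by
   at least 0.4 s above 30% of the largest peak become fiducials. On
   synthetic data the true fiducials are known, so detection accuracy is
   testable (≥95% of beats within 50 ms at default noise); recordings that
   already carry fiducials bypass detection, which gives tests an oracle
   path.
2. **Ensemble averaging** (`ensembleAverage()`): beats are extracted in a
   window spanning 0–80% of the median RR interval after each fiducial,
   resampled to a fixed 512-point grid, outliers with Pearson correlation
   < 0.5 against the point-wise median beat are rejected, and at least 15
   surviving beats are averaged point-wise. Averaging B beats reduces
   uncorrelated noise by √B, a property the test suite checks against the
   closed form.
3. **Feature extraction** (`fitFeatureBasis()`, `extractFeatures()`): the
   systolic window is the first 300 ms after the fiducial; its Hann-windowed
   magnitude spectrum (FFT zero-padded to 256 points, bins ≤ 50 Hz) enters
   a PCA across training beats. The diastolic window is 50–80% of the
   median RR. Both PC-1 loadings are sign-oriented so their training scores
   correlate positively with the corresponding spectral centroid — a
   deterministic, data-only convention that removes the PCA sign ambiguity
   which would otherwise flip regression coefficients between runs.

The window bounds are explicit package choices: the source literature names
the systolic and diastolic complexes but does not publish the device's
window definitions, so these bounds are stand-ins that cleanly isolate the
two bursts of the synthetic beat model, and they are recorded in the
persisted `FeatureBasis` so extraction is always consistent with training.

## The synthetic-data generators

`generateCohort()` draws demographics matching the validation study's
baseline table: 107 recruited subjects, 52.1% female, age 48.2 (8.7) years,
weight 76.5 (13.9) kg, height 1.77 (0.08) m, half active (≥5 h
exercise/week). Latent true fitness follows

`vo2 = 52.717 − 7·female − 0.35·age + 10·active + N(0, 5.2)`

calibrated once so the cohort mean/SD is ≈ 37.2 (8.6) mL/min/kg and the
active–sedentary gap ≈ 10 mL/min/kg, as published; the individual
coefficients are free parameters of the generator, not estimates of any
real population. Eleven subjects are flagged for premature CPET termination
and two for device battery failure, reproducing the published exclusion
flow 107 → 94.

`simulateScg()` builds each heartbeat from two Gaussian-windowed cosine
("Gabor") bursts — analytically tractable, which enables closed-form test
oracles:

* the systolic burst, centered on the fiducial, with center frequency
  `15 + 0.2·vo2` Hz;
* the diastolic burst at 65% of the nominal RR interval, whose peak-to-peak
  amplitude is `0.3 + 0.01·vo2` m/s² (templates are normalized to unit
  peak-to-peak, so this value is exact by construction) and whose shape
  interpolates between a 6-Hz and a 10-Hz template with a logistic blend
  `plogis(0.05·(vo2 − 37.2))`.

Resting heart rate is `60.1 − 0.5·(vo2 − 37.2)` BPM plus a stable
subject-level offset (SD 8 BPM) and small within-recording noise; the
post-exercise condition shifts the mean to 82.0 BPM (matching the published
rest/post heart rates of 60.1 and 82.0) and attenuates the diastolic
amplitude by factor 0.85 — the published observation is only that the
post-exercise estimate drops, not the mechanism, so the attenuation is a
modeling choice. Beat intervals get Gaussian jitter (SD 20 ms), the trace
white noise (SD 0.05 m/s²), and burst centers are snapped to the sample
grid so the zero-noise limit produces exactly identical beats — the
degeneracy several tests rely on. The true slopes coupling the features to
fitness inside the real device are unknown; the generator's slopes are free
parameters chosen to give realistic effect sizes, and the monotone-coupling
tests verify the *pipeline* recovers whatever the generator encodes.

`simulateCpet()` emulates the ramp protocol: 3 min at 50 W, then +1 W every
3.6 s (implemented stepwise with a 1e-6 epsilon inside the floor to keep
step-boundary times on the new step despite floating-point representation).
Oxygen uptake follows first-order kinetics (τ = 30 s) toward
`350 + 10.8·power` mL/min capped at the subject's true absolute VO2max;
heart rate rises with the uptake fraction toward the Tanaka maximum; the
respiratory exchange ratio rises quadratically and crosses 1.05 at 75% of
full effort. Unflagged subjects continue 35 s past the uptake plateau so
the last-30-s window satisfies both exhaustion criteria (heart rate > 90%
of Tanaka maximum *and* RER > 1.05, both strict); flagged subjects stop at
70% of their attainable uptake and fail both.

What the generators deliberately do **not** emulate: respiration-phase
modulation of the SCG, multi-axis sensors, arrhythmia or disease states,
gas-analyzer drift, or any correlation structure beyond the documented
fitness couplings. Passing tests therefore demonstrate that the pipeline's
statistics and signal path are correct, not that the device's accuracy on
real humans is reproduced.

## Extraction and validation statistics

`computeVo2max()` defines VO2max and HRmax as the time-weighted
(trapezoidal) means of VO2 and heart rate over the final 30 s of loaded
exercise, interpolating the window's left edge because breath intervals are
irregular; the final RER is the time-weighted mean of VCO2/VO2 over the
same window (the source protocol does not state whether the end-exercise
quotient is instantaneous or averaged; the 30-s mean was chosen for
symmetry with VO2max). The cool-down is excluded: the trace ends at
termination of loaded exercise.

`agreementReport()` computes, for one estimator against the reference:
bias with paired-t 95% CI and p-value; MAPE (mean of 100·|est−ref|/ref)
with a t-interval on the per-subject absolute percentage errors (the
source reports MAPE CIs without stating a method; the t-interval is the
simplest choice and its coverage is verified by simulation); Pearson r with
Fisher-z CI; SEE as the residual SD (divisor n−2) of the regression of
reference on estimate — the validation-literature convention, since no
formula is published; and Bland–Altman limits of agreement bias ±
1.96·SD(differences), whose width identity (3.92·SD) holds to 1e-9 by
construction. Degenerate inputs (zero-variance differences, e.g. a perfect
or constant-offset estimator) collapse the intervals to a point rather than
erroring, and a zero reference raises an explicit MAPE-undefined error.

Repeatability uses `iccAbsoluteAgreement()` — the two-way random-effects,
single-measurement, absolute-agreement ICC(A,1), the only variant
consistent with "absolute agreement" for one device measured twice:

$$ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}$$

computed from the two-way crossed mean squares and verified against an
independent brute-force ANOVA oracle to 1e-10. `steigerTest()` compares two
dependent correlations sharing the reference variable via the
Fisher-transformed difference scaled by the Steiger (1980) covariance term
evaluated at the back-transformed mean correlation (the variant is
unstated in the source; this choice is validated against a 10,000-replicate
parametric bootstrap to within 0.01 in p). `compareMape()` applies the
paired t-test to per-subject APE differences, and `rmsDifference()` the
root-mean-square difference. `subgroupAnalysis()` stratifies by sex, age
(< 50 vs ≥ 50 years), lifestyle, BMI (< 25 / 25–29.9 / ≥ 30) and reference
fitness (< 30 / 30–44.9 / ≥ 45 mL/min/kg), flagging strata with fewer than
three pairs as insufficient rather than reporting unstable statistics.

## The study pipeline

`runStudy()` chains everything: cohort → CPET for every subject → exclusion
rules → two rest SCG recordings and one post-exercise recording per
included subject (fiducials are stripped and re-detected, so the honest
signal path is exercised) → PCA basis on the first rest recording → SCG
model fitted with 5-fold cross-validation, each subject predicted by the
model trained without their fold (fitting and evaluating on the same
subjects would inflate agreement; the real device was trained on external
data) → FRIENDS and ACSM benchmarks → agreement tables for every estimator,
repeatability block (ICC, MAPE, RMS between the two rest recordings), a
Table-1-style baseline summary, Table-3-style subgroup table, exclusion
tally, and full provenance (master seed, config hash, versions). One master
seed fans out deterministically via `childSeed()`; identical configurations
give byte-identical outputs. The subgroup analysis uses the average of the
two rest estimates, as the source's subgroup table does; per-recording
tables are available from the same report.

Default problem sizes were chosen so a full default study (107 subjects,
three recordings each) runs in well under a minute on one core; the test
suite uses cohorts of 25–150 subjects, 100-replicate Monte-Carlo checks and
1000–2000-replicate coverage simulations, sizes at which the verified
tolerances (20% on the √B noise law, ±2% coverage, 0.01 on bootstrap
p-agreement) are comfortably resolvable.

## Known limitations

* The SCG model is plain OLS on four fixed features; no attempt is made to
  reproduce the proprietary training pipeline, its feature windows, or its
  trained coefficients, and subject-level published results (r ≈ 0.83,
  MAPE ≈ 11%) are not reproducible without the unavailable raw data. The
  default synthetic study is in fact considerably *cleaner* than a real
  one — the generator's feature couplings are exact up to configured noise,
  with none of the unmodeled physiological variability of real subjects —
  so its agreement statistics should be read as structural output, not as
  device accuracy.
* Generator slopes, noise levels and the post-exercise attenuation are
  package choices constrained only by published group summaries.
* The exhaustion criteria use strict inequalities as printed; a last-30-s
  mean RER of exactly 1.05 fails.
* `ramp_power` treats the ramp as 1-W steps; times within 3.6 µs of a step
  boundary may land on either side.

## Session info

```{r}
sessionInfo()
```
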