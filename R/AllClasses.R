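# S4 container classes. Constructors live next to the code that builds the
# objects; validity methods enforce the structural invariants.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' SCGRecording: a single-axis seismocardiography recording
#'
#' Uniform-rate sternal acceleration trace, optionally carrying the true
#' beat fiducial times (s). Synthetic recordings produced by [simulateScg()]
#' always carry fiducials (the systolic-complex centers) plus generator
#' ground truth in `meta`; recordings read from disk may not.
#'
#' @slot samples numeric, acceleration in m/s^2.
#' @slot fs numeric scalar, sampling rate in Hz.
#' @slot fiducials numeric or NULL, strictly increasing beat times in s.
#' @slot condition character, `"rest"` or `"post_exercise"`.
#' @slot meta list of generator ground truth (may be empty).
#' @export
setClass("SCGRecording",
  representation(samples = "numeric", fs = "numeric",
                 fiducials = "numericOrNULL", condition = "character",
                 meta = "list"),
  prototype(meta = list(), condition = "rest"))

setValidity("SCGRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs < 100)
    msg <- c(msg, "fs must be a single value >= 100 Hz")
  if (!object@condition %in% c("rest", "post_exercise"))
    msg <- c(msg, "condition must be 'rest' or 'post_exercise'")
  if (!is.null(object@fiducials) && length(object@fiducials)) {
    dur <- length(object@samples) / object@fs
    if (any(diff(object@fiducials) <= 0))
      msg <- c(msg, "fiducials must be strictly increasing")
    if (min(object@fiducials) < 0 || max(object@fiducials) > dur)
      msg <- c(msg, "fiducials must lie inside the record")
  }
  if (length(msg)) msg else TRUE
})

#' EnsembleBeat: the ensemble-average SCG heartbeat
#'
#' Point-wise average of fiducial-aligned beats, resampled to a fixed-length
#' grid spanning 0 to 80% of the median beat-to-beat (RR) interval.
#'
#' @slot waveform numeric, averaged beat (m/s^2) on the fixed grid.
#' @slot fs numeric, native sampling rate of the source recording (Hz).
#' @slot windowSec numeric, duration spanned by the grid (s).
#' @slot nBeatsUsed integer, beats entering the average.
#' @slot nBeatsRejected integer, beats rejected as outliers.
#' @slot rrMean numeric, mean RR interval (ms).
#' @slot rrSd numeric, SD of RR intervals (ms).
#' @export
setClass("EnsembleBeat",
  representation(waveform = "numeric", fs = "numeric", windowSec = "numeric",
                 nBeatsUsed = "integer", nBeatsRejected = "integer",
                 rrMean = "numeric", rrSd = "numeric"))

setValidity("EnsembleBeat", function(object) {
  msg <- character()
  if (object@nBeatsUsed < 1L) msg <- c(msg, "nBeatsUsed must be >= 1")
  if (object@nBeatsRejected < 0L) msg <- c(msg, "nBeatsRejected must be >= 0")
  if (object@rrMean <= 0) msg <- c(msg, "rrMean must be positive (ms)")
  if (object@windowSec <= 0) msg <- c(msg, "windowSec must be positive")
  if (length(msg)) msg else TRUE
})

#' FeatureBasis: PCA basis for the SCG waveform features
#'
#' First principal component of the centered diastolic-window waveforms and
#' of the centered systolic magnitude spectra, fitted on a training set of
#' ensemble beats, with deterministic sign conventions (scores correlate
#' positively with the respective spectral centroid).
#'
#' @slot diaMean numeric, training mean of the diastolic window.
#' @slot diaLoadings numeric, unit-norm diastolic PC-1 loading vector.
#' @slot sysMean numeric, training mean systolic magnitude spectrum.
#' @slot sysLoadings numeric, unit-norm systolic PC-1 loading vector.
#' @slot sysFreqs numeric, frequency bins of the systolic spectrum (Hz).
#' @slot nTraining integer, training-set size.
#' @slot windows list of window parameters (see [scgWindows()]).
#' @export
setClass("FeatureBasis",
  representation(diaMean = "numeric", diaLoadings = "numeric",
                 sysMean = "numeric", sysLoadings = "numeric",
                 sysFreqs = "numeric", nTraining = "integer",
                 windows = "list"))

setValidity("FeatureBasis", function(object) {
  msg <- character()
  if (abs(sqrt(sum(object@diaLoadings^2)) - 1) > 1e-8)
    msg <- c(msg, "diaLoadings must be unit norm")
  if (abs(sqrt(sum(object@sysLoadings^2)) - 1) > 1e-8)
    msg <- c(msg, "sysLoadings must be unit norm")
  if (length(object@diaMean) != length(object@diaLoadings))
    msg <- c(msg, "diaMean and diaLoadings lengths differ")
  if (length(object@sysMean) != length(object@sysLoadings) ||
      length(object@sysMean) != length(object@sysFreqs))
    msg <- c(msg, "systolic basis dimensions inconsistent")
  if (object@nTraining < 2L) msg <- c(msg, "nTraining must be >= 2")
  if (length(msg)) msg else TRUE
})

#' ScgVo2Model: linear SCG regression for relative VO2max
#'
#' Ordinary-least-squares fit of relative VO2max (mL/min/kg) on sex, age,
#' weight, height and the four SCG features (RR, diastolic peak-to-peak,
#' diastolic morphology score, systolic spectrum score).
#'
#' @slot coefficients named numeric, the nine regression coefficients.
#' @slot se named numeric, coefficient standard errors.
#' @slot fitN integer, rows used in the fit.
#' @slot residualSd numeric, residual standard deviation (mL/min/kg).
#' @export
setClass("ScgVo2Model",
  representation(coefficients = "numeric", se = "numeric",
                 fitN = "integer", residualSd = "numeric"))

setValidity("ScgVo2Model", function(object) {
  msg <- character()
  if (object@fitN <= length(object@coefficients))
    msg <- c(msg, "fitN must exceed the number of parameters")
  if (object@residualSd < 0) msg <- c(msg, "residualSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' PairedScores: aligned estimator/reference VO2max pairs
#'
#' @slot ids character, subject ids.
#' @slot estimate numeric, estimator values (mL/min/kg).
#' @slot reference numeric, reference (CPET) values (mL/min/kg).
#' @slot nDropped integer, incomplete pairs dropped at construction.
#' @export
setClass("PairedScores",
  representation(ids = "character", estimate = "numeric",
                 reference = "numeric", nDropped = "integer"))

setValidity("PairedScores", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (length(object@estimate) != n || length(object@reference) != n)
    msg <- c(msg, "ids, estimate and reference must have equal length")
  if (n < 3L) msg <- c(msg, "at least 3 complete pairs are required")
  if (anyNA(object@estimate) || anyNA(object@reference))
    msg <- c(msg, "missing values must be dropped at construction")
  if (anyDuplicated(object@ids)) msg <- c(msg, "ids must be unique")
  if (length(msg)) msg else TRUE
})

#' AgreementReport: method-comparison summary for one estimator
#'
#' Bias with 95% CI and paired-t p-value, MAPE with 95% CI, Pearson r with
#' Fisher-z 95% CI, SEE, and Bland-Altman limits of agreement.
#'
#' @slot n integer, pairs analysed.
#' @slot bias numeric, mean(estimate - reference), mL/min/kg.
#' @slot biasCI numeric length 2.
#' @slot biasP numeric, paired-t p-value.
#' @slot mape numeric, mean absolute percentage error (%).
#' @slot mapeCI numeric length 2.
#' @slot r numeric, Pearson correlation.
#' @slot rCI numeric length 2 (Fisher z).
#' @slot see numeric, standard error of estimate, mL/min/kg.
#' @slot loa numeric length 2, lower and upper limits of agreement.
#' @export
setClass("AgreementReport",
  representation(n = "integer", bias = "numeric", biasCI = "numeric",
                 biasP = "numeric", mape = "numeric", mapeCI = "numeric",
                 r = "numeric", rCI = "numeric", see = "numeric",
                 loa = "numeric"))

setValidity("AgreementReport", function(object) {
  msg <- character()
  if (object@mape < 0) msg <- c(msg, "mape must be >= 0")
  if (length(object@loa) != 2L || object@loa[2L] < object@loa[1L])
    msg <- c(msg, "loa must be c(lower, upper) with upper >= lower")
  if (length(msg)) msg else TRUE
})

#' ICCResult: two-way absolute-agreement intraclass correlation
#'
#' @slot value numeric, the ICC.
#' @slot variant character, e.g. "ICC(A,1)".
#' @slot msr,msc,mse numeric, the two-way mean squares.
#' @slot n,k integer, subjects and repeated measurements.
#' @export
setClass("ICCResult",
  representation(value = "numeric", variant = "character", msr = "numeric",
                 msc = "numeric", mse = "numeric", n = "integer",
                 k = "integer"))

setValidity("ICCResult", function(object) {
  if (object@value > 1 + 1e-12) "ICC cannot exceed 1" else TRUE
})

#' SteigerResult: test for two dependent correlations
#'
#' @slot z numeric, the test statistic.
#' @slot p numeric, two-sided p-value.
#' @slot r1,r2 numeric, the two correlations sharing the reference variable.
#' @slot r12 numeric, correlation between the two estimators.
#' @slot n integer, sample size.
#' @export
setClass("SteigerResult",
  representation(z = "numeric", p = "numeric", r1 = "numeric", r2 = "numeric",
                 r12 = "numeric", n = "integer"))

setValidity("SteigerResult", function(object) {
  msg <- character()
  if (object@p < 0 || object@p > 1) msg <- c(msg, "p must lie in [0, 1]")
  if (sign(object@z) != 0 && sign(object@z) != sign(object@r1 - object@r2) &&
      abs(object@r1 - object@r2) > 1e-12)
    msg <- c(msg, "z sign must match r1 - r2")
  if (length(msg)) msg else TRUE
})

#' StudyReport: full output of one synthetic validation study
#'
#' @slot baseline data.frame, Table-1-style cohort characteristics.
#' @slot agreement data.frame, Table-2-style per-estimator statistics.
#' @slot subgroups data.frame, Table-3-style stratified statistics.
#' @slot repeatability list with ICC, MAPE and RMS between the two rest
#'   recordings.
#' @slot exclusions named integer, exclusion tally by reason.
#' @slot predictions data.frame, per-subject estimates and reference values.
#' @slot provenance list: master seed, config hash, package/R versions.
#' @export
setClass("StudyReport",
  representation(baseline = "data.frame", agreement = "data.frame",
                 subgroups = "data.frame", repeatability = "list",
                 exclusions = "integer", predictions = "data.frame",
                 provenance = "list"))
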