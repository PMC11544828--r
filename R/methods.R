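# Accessor and show methods.

#' @rdname scgvo2-accessors
#' @export
setMethod("samples", "SCGRecording", function(x) x@samples)

#' @rdname scgvo2-accessors
#' @export
setMethod("sampleRate", "SCGRecording", function(x) x@fs)

#' @rdname scgvo2-accessors
#' @export
setMethod("fiducialTimes", "SCGRecording", function(x) x@fiducials)

#' @rdname scgvo2-accessors
#' @export
setMethod("recordingCondition", "SCGRecording", function(x) x@condition)

#' @rdname scgvo2-accessors
#' @export
setMethod("waveform", "EnsembleBeat", function(x) x@waveform)

#' @rdname scgvo2-accessors
#' @export
setMethod("sampleRate", "EnsembleBeat", function(x) x@fs)

#' @rdname scgvo2-accessors
#' @export
setMethod("rrMean", "EnsembleBeat", function(x) x@rrMean)

#' @rdname scgvo2-accessors
#' @export
setMethod("nBeatsUsed", "EnsembleBeat", function(x) x@nBeatsUsed)

#' @rdname scgvo2-accessors
#' @export
setMethod("nBeatsRejected", "EnsembleBeat", function(x) x@nBeatsRejected)

#' @describeIn ScgVo2Model-class coefficients of the fitted model.
#' @param object a `ScgVo2Model`.
#' @param ... ignored.
#' @export
setMethod("coef", "ScgVo2Model", function(object, ...) object@coefficients)

setMethod("show", "SCGRecording", function(object) {
  cat(sprintf("SCGRecording: %.1f s at %g Hz (%s), %s fiducials\n",
              length(object@samples) / object@fs, object@fs,
              object@condition,
              if (is.null(object@fiducials)) "no"
              else length(object@fiducials)))
})

setMethod("show", "EnsembleBeat", function(object) {
  cat(sprintf(
    "EnsembleBeat: %d-point window (%.3f s), %d beats used, %d rejected\n",
    length(object@waveform), object@windowSec, object@nBeatsUsed,
    object@nBeatsRejected))
  cat(sprintf("  RR %.1f (SD %.1f) ms\n", object@rrMean, object@rrSd))
})

setMethod("show", "FeatureBasis", function(object) {
  cat(sprintf(
    "FeatureBasis: dia PC-1 (%d points), sys PC-1 (%d bins <= %.1f Hz), fitted on %d beats\n",
    length(object@diaLoadings), length(object@sysLoadings),
    max(object@sysFreqs), object@nTraining))
})

setMethod("show", "ScgVo2Model", function(object) {
  cat("ScgVo2Model (OLS)\n")
  print(round(object@coefficients, 5))
  cat(sprintf("  n = %d, residual SD = %.3f mL/min/kg\n",
              object@fitN, object@residualSd))
})

setMethod("show", "PairedScores", function(object) {
  cat(sprintf("PairedScores: %d pairs (%d dropped)\n",
              length(object@ids), object@nDropped))
})

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf("AgreementReport (n = %d)\n", object@n))
  cat(sprintf("  bias %.2f [%.2f, %.2f] mL/min/kg, p = %.3g\n",
              object@bias, object@biasCI[1], object@biasCI[2], object@biasP))
  cat(sprintf("  MAPE %.1f%% [%.1f, %.1f]\n",
              object@mape, object@mapeCI[1], object@mapeCI[2]))
  cat(sprintf("  r %.3f [%.3f, %.3f], SEE %.2f mL/min/kg\n",
              object@r, object@rCI[1], object@rCI[2], object@see))
  cat(sprintf("  LoA [%.2f, %.2f] mL/min/kg\n",
              object@loa[1], object@loa[2]))
})

setMethod("show", "ICCResult", function(object) {
  cat(sprintf("%s = %.4f (n = %d, k = %d)\n", object@variant, object@value,
              object@n, object@k))
})

setMethod("show", "SteigerResult", function(object) {
  cat(sprintf(
    "Steiger test: r1 = %.3f vs r2 = %.3f (r12 = %.3f, n = %d): z = %.3f, p = %.4g\n",
    object@r1, object@r2, object@r12, object@n, object@z, object@p))
})

setMethod("show", "StudyReport", function(object) {
  cat("StudyReport\n")
  cat(sprintf("  included subjects: %d\n", object@provenance$nIncluded))
  cat("  exclusions:\n")
  for (nm in names(object@exclusions))
    cat(sprintf("    %s: %d\n", nm, object@exclusions[[nm]]))
  cat(sprintf("  estimators compared: %s\n",
              paste(unique(object@agreement$estimator), collapse = ", ")))
  cat(sprintf("  master seed: %d\n", object@provenance$seed))
})
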