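# Plain-text persistence: cohorts, recordings and CPET traces as CSV,
# feature bases and fitted models as JSON.

#' Read and write scgvo2 objects as plain text
#'
#' Cohorts, CPET traces and feature tables round-trip as headered CSV.
#' An [SCGRecording-class] is written as a two-column CSV (`time`, `accel`)
#' plus a JSON sidecar (`<path>.json`) carrying the sampling rate, the
#' condition and any fiducial times. A [FeatureBasis-class] or
#' [ScgVo2Model-class] round-trips as a single JSON document.
#'
#' @param x the object (or data.frame) to write.
#' @param path file path.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @name scgvo2-io
NULL

#' @rdname scgvo2-io
#' @export
writeCohortCsv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname scgvo2-io
#' @export
readCohortCsv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname scgvo2-io
#' @export
writeCpetTraceCsv <- writeCohortCsv

#' @rdname scgvo2-io
#' @export
readCpetTraceCsv <- readCohortCsv

#' @rdname scgvo2-io
#' @export
writeFeatureTableCsv <- writeCohortCsv

#' @rdname scgvo2-io
#' @export
readFeatureTableCsv <- readCohortCsv

#' @rdname scgvo2-io
#' @export
writeRecordingCsv <- function(x, path) {
  stopifnot(methods::is(x, "SCGRecording"))
  df <- data.frame(time = (seq_along(samples(x)) - 1L) / sampleRate(x),
                   accel = samples(x))
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(fs = sampleRate(x), condition = recordingCondition(x),
               fiducials = fiducialTimes(x))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname scgvo2-io
#' @export
readRecordingCsv <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  fid <- side$fiducials
  if (length(fid) == 0L) fid <- NULL
  methods::new("SCGRecording", samples = df$accel, fs = side$fs,
               fiducials = fid, condition = side$condition, meta = list())
}

#' @rdname scgvo2-io
#' @export
writeBasisJson <- function(x, path) {
  stopifnot(methods::is(x, "FeatureBasis"))
  obj <- list(dia_mean = x@diaMean, dia_loadings = x@diaLoadings,
              sys_mean = x@sysMean, sys_loadings = x@sysLoadings,
              sys_freqs = x@sysFreqs, n_training = x@nTraining,
              windows = x@windows)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname scgvo2-io
#' @export
readBasisJson <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- o$windows
  methods::new("FeatureBasis", diaMean = o$dia_mean,
               diaLoadings = o$dia_loadings, sysMean = o$sys_mean,
               sysLoadings = o$sys_loadings, sysFreqs = o$sys_freqs,
               nTraining = as.integer(o$n_training),
               windows = scgWindows(gridN = w$gridN,
                                    windowFrac = w$windowFrac,
                                    sysWinSec = w$sysWinSec,
                                    diaFrac = w$diaFrac,
                                    maxFreq = w$maxFreq, nfft = w$nfft,
                                    minBeats = w$minBeats,
                                    outlierR = w$outlierR))
}

#' @rdname scgvo2-io
#' @export
writeModelJson <- function(x, path) {
  stopifnot(methods::is(x, "ScgVo2Model"))
  obj <- list(coefficients = as.list(x@coefficients), se = as.list(x@se),
              fit_n = x@fitN, residual_sd = x@residualSd,
              units = list(rr_ms = "ms", weight = "kg", height = "m",
                           response = "mL/min/kg",
                           sex = "0 = male, 1 = female"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname scgvo2-io
#' @export
readModelJson <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("ScgVo2Model", coefficients = unlist(o$coefficients),
               se = unlist(o$se), fitN = as.integer(o$fit_n),
               residualSd = o$residual_sd)
}
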