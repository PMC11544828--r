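# Generics for the S4 containers. Accessors are preferred over direct slot
# access throughout the package and its documentation.

#' @name scgvo2-accessors
#' @title Accessor generics for scgvo2 objects
#' @description Small accessor generics for the package's S4 containers:
#'   acceleration samples, sampling rate, beat fiducials, recording condition,
#'   averaged waveform and beat-bookkeeping counts.
#' @param x an object of the documented class.
#' @return The slot value (see the class documentation for units).
NULL

#' @rdname scgvo2-accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname scgvo2-accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname scgvo2-accessors
#' @export
setGeneric("fiducialTimes", function(x) standardGeneric("fiducialTimes"))

#' @rdname scgvo2-accessors
#' @export
setGeneric("recordingCondition", function(x) standardGeneric("recordingCondition"))

#' @rdname scgvo2-accessors
#' @export
setGeneric("waveform", function(x) standardGeneric("waveform"))

#' @rdname scgvo2-accessors
#' @export
setGeneric("rrMean", function(x) standardGeneric("rrMean"))

#' @rdname scgvo2-accessors
#' @export
setGeneric("nBeatsUsed", function(x) standardGeneric("nBeatsUsed"))

#' @rdname scgvo2-accessors
#' @export
setGeneric("nBeatsRejected", function(x) standardGeneric("nBeatsRejected"))

#' Predict relative VO2max from a fitted SCG regression model
#'
#' @param object a fitted model (see [fitScgVo2Model()]).
#' @param newdata data.frame of predictor rows.
#' @return Numeric vector of VO2max estimates in mL/min/kg.
#' @export
setGeneric("predictVo2", function(object, newdata) standardGeneric("predictVo2"))
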