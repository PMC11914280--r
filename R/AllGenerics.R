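#' Accessors for package classes
#'
#' Small accessor layer so user code never touches slots directly:
#' `patients()`, `bloodDraws()`, `survivalRecords()`, `trueFractions()`,
#' `expressionMatrices()`, `ihcDensities()` and `cohortConfigOf()` read the
#' components of a [SyntheticCohort-class]; `cellScores()`, `deconvMethod()`
#' and `sampleInfo()` read a [DeconvResult-class]; `selectedThreshold()`,
#' `aucOf()` and `rocCurve()` read a [ThresholdSelection-class].
#'
#' @param object an object of the documented class.
#' @return The corresponding component (data.frame, matrix, list or scalar).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("patients", function(object) standardGeneric("patients"))
#' @rdname accessors
#' @export
setGeneric("bloodDraws", function(object) standardGeneric("bloodDraws"))
#' @rdname accessors
#' @export
setGeneric("survivalRecords", function(object) standardGeneric("survivalRecords"))
#' @rdname accessors
#' @export
setGeneric("trueFractions", function(object) standardGeneric("trueFractions"))
#' @rdname accessors
#' @export
setGeneric("expressionMatrices", function(object) standardGeneric("expressionMatrices"))
#' @rdname accessors
#' @export
setGeneric("ihcDensities", function(object) standardGeneric("ihcDensities"))
#' @rdname accessors
#' @export
setGeneric("cohortConfigOf", function(object) standardGeneric("cohortConfigOf"))
#' @rdname accessors
#' @export
setGeneric("cellScores", function(object) standardGeneric("cellScores"))
#' @rdname accessors
#' @export
setGeneric("deconvMethod", function(object) standardGeneric("deconvMethod"))
#' @rdname accessors
#' @export
setGeneric("sampleInfo", function(object) standardGeneric("sampleInfo"))
#' @rdname accessors
#' @export
setGeneric("selectedThreshold", function(object) standardGeneric("selectedThreshold"))
#' @rdname accessors
#' @export
setGeneric("aucOf", function(object) standardGeneric("aucOf"))
#' @rdname accessors
#' @export
setGeneric("rocCurve", function(object) standardGeneric("rocCurve"))

#' @rdname accessors
setMethod("patients", "SyntheticCohort", function(object) object@patients)
#' @rdname accessors
setMethod("bloodDraws", "SyntheticCohort", function(object) object@blood)
#' @rdname accessors
setMethod("survivalRecords", "SyntheticCohort", function(object) object@survival)
#' @rdname accessors
setMethod("trueFractions", "SyntheticCohort", function(object) object@trueFractions)
#' @rdname accessors
setMethod("expressionMatrices", "SyntheticCohort", function(object) object@expression)
#' @rdname accessors
setMethod("ihcDensities", "SyntheticCohort", function(object) object@ihc)
#' @rdname accessors
setMethod("cohortConfigOf", "SyntheticCohort", function(object) object@config)
#' @rdname accessors
setMethod("cellScores", "DeconvResult", function(object) object@scores)
#' @rdname accessors
setMethod("deconvMethod", "DeconvResult", function(object) object@method)
#' @rdname accessors
setMethod("sampleInfo", "DeconvResult", function(object) object@sampleInfo)
#' @rdname accessors
setMethod("selectedThreshold", "ThresholdSelection", function(object) object@threshold)
#' @rdname accessors
setMethod("aucOf", "ThresholdSelection", function(object) object@auc)
#' @rdname accessors
setMethod("rocCurve", "ThresholdSelection", function(object) object@roc)
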