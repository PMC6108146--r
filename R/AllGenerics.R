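#' @rdname Cohort-accessors
#' @export
setGeneric("exprData", function(x) standardGeneric("exprData"))

#' @rdname Cohort-accessors
#' @export
setGeneric("methData", function(x) standardGeneric("methData"))

#' @rdname Cohort-accessors
#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))

#' @rdname Cohort-accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' Accessors for Cohort components
#'
#' \code{exprData} and \code{methData} return the expression and
#' methylation \code{SummarizedExperiment}s, \code{clinicalData} the
#' clinical \code{DataFrame} and \code{sampleIDs} the shared ordered
#' sample axis.
#'
#' @param x A \linkS4class{Cohort}.
#' @return The requested component.
#' @name Cohort-accessors
#' @aliases exprData,Cohort-method methData,Cohort-method
#'   clinicalData,Cohort-method sampleIDs,Cohort-method
NULL

#' @rdname Cohort-accessors
setMethod("exprData", "Cohort", function(x) x@expression)

#' @rdname Cohort-accessors
setMethod("methData", "Cohort", function(x) x@methylation)

#' @rdname Cohort-accessors
setMethod("clinicalData", "Cohort", function(x) x@clinical)

#' @rdname Cohort-accessors
setMethod("sampleIDs", "Cohort", function(x) colnames(x@expression))
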