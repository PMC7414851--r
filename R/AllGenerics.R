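#' @import methods
NULL

#' @rdname ContactMatrix-class
#' @export
setGeneric("contactCounts", function(x) standardGeneric("contactCounts"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("binMask", function(x) standardGeneric("binMask"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname QuantileProfile-class
#' @export
setGeneric("profileSummary", function(x) standardGeneric("profileSummary"))

#' @rdname QuantileProfile-class
#' @export
setGeneric("quantileMembers", function(x) standardGeneric("quantileMembers"))

#' @rdname QuantileProfile-class
#' @export
setGeneric("quantileValues", function(x) standardGeneric("quantileValues"))

#' @rdname PlaResult-class
#' @export
setGeneric("fociCounts", function(x) standardGeneric("fociCounts"))

#' @rdname PlaResult-class
#' @export
setGeneric("conditionName", function(x) standardGeneric("conditionName"))
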