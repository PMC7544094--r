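#' @rdname LDMatrix-class
#' @param object,x an \code{LDMatrix} or \code{AttributionReport}.
#' @export
setGeneric("ldChromosome", function(x) standardGeneric("ldChromosome"))

#' @rdname LDMatrix-class
#' @export
setGeneric("ldRsids", function(x) standardGeneric("ldRsids"))

#' @rdname LDMatrix-class
#' @export
setGeneric("ldValues", function(x) standardGeneric("ldValues"))

#' @rdname LDMatrix-class
#' @export
setMethod("ldChromosome", "LDMatrix", function(x) x@chromosome)

#' @rdname LDMatrix-class
#' @export
setMethod("ldRsids", "LDMatrix", function(x) x@rsids)

#' @rdname LDMatrix-class
#' @export
setMethod("ldValues", "LDMatrix", function(x) x@r2)

#' @rdname AttributionReport-class
#' @export
setGeneric("excessRows", function(x) standardGeneric("excessRows"))

#' @rdname AttributionReport-class
#' @export
setGeneric("excessTotals", function(x) standardGeneric("excessTotals"))

#' @rdname AttributionReport-class
#' @export
setGeneric("excludedCauses", function(x) standardGeneric("excludedCauses"))

#' @rdname AttributionReport-class
#' @export
setGeneric("includedPairs", function(x) standardGeneric("includedPairs"))

#' @rdname AttributionReport-class
#' @export
setMethod("excessRows", "AttributionReport", function(x) x@rows)

#' @rdname AttributionReport-class
#' @export
setMethod("excessTotals", "AttributionReport", function(x) x@totals)

#' @rdname AttributionReport-class
#' @export
setMethod("excludedCauses", "AttributionReport", function(x) x@excluded)

#' @rdname AttributionReport-class
#' @export
setMethod("includedPairs", "AttributionReport", function(x) x@included)
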