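#' @rdname ctValues
#' @export
setGeneric("ctValues", function(x) standardGeneric("ctValues"))

#' @rdname ctValues
#' @export
setGeneric("deltaCtValues", function(x) standardGeneric("deltaCtValues"))

#' @rdname ctValues
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname ctValues
#' @export
setGeneric("controlIds", function(x) standardGeneric("controlIds"))

#' @rdname deltaCt
#' @export
setGeneric("deltaCt", function(x, ...) standardGeneric("deltaCt"))

#' @rdname degrees
#' @export
setGeneric("degrees", function(x, side = c("both", "left", "right"))
  standardGeneric("degrees"))

#' @rdname degrees
#' @export
setGeneric("weightedDegrees", function(x, side = c("both", "left", "right"))
  standardGeneric("weightedDegrees"))

#' @rdname asIgraph
#' @export
setGeneric("asIgraph", function(x, ...) standardGeneric("asIgraph"))

#' @rdname runEnrichment
#' @export
setGeneric("enrichmentTable", function(x) standardGeneric("enrichmentTable"))
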