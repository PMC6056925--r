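#' @rdname InteractionNetwork-class
#' @param x an object.
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))

#' @rdname GeneSet-class
#' @param x an object.
#' @export
setGeneric("symbols", function(x) standardGeneric("symbols"))

#' @rdname GeneSet-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname Module-class
#' @param x an object.
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname Module-class
#' @export
setGeneric("moduleScore", function(x) standardGeneric("moduleScore"))

#' @rdname ModuleSet-class
#' @param x an object.
#' @export
setGeneric("modules", function(x) standardGeneric("modules"))

#' @rdname SeededNetwork-class
#' @param x an object.
#' @export
setGeneric("seedsUsed", function(x) standardGeneric("seedsUsed"))

#' @rdname ExpressionData-class
#' @param x an object.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ExpressionData-class
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname GeneSetCollection-class
#' @param x an object.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
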