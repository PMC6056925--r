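#' @import methods
NULL

NODE_CATEGORIES <- c("BOTH", "DISEASE_ONLY", "IMMUNE_ONLY", "OTHER")

#' GeneSet: a named collection of gene symbols
#'
#' A seed gene collection (e.g. an immune annotation export or a
#' disease-gene list). Symbols are stored uppercased and deduplicated;
#' \code{provenance} records where the set came from.
#'
#' @slot name single character label.
#' @slot symbols character vector of normalized gene symbols.
#' @slot provenance free-text source descriptor (file, database, version).
#' @export
setClass("GeneSet",
    representation(name = "character", symbols = "character",
                   provenance = "character"),
    prototype(name = NA_character_, symbols = character(0),
              provenance = ""))

setValidity("GeneSet", function(object) {
    msgs <- character(0)
    if (length(object@name) != 1L)
        msgs <- c(msgs, "'name' must be a single string")
    s <- object@symbols
    if (anyNA(s) || any(!nzchar(s)))
        msgs <- c(msgs, "symbols must be non-empty strings")
    if (any(grepl("\\s", s)))
        msgs <- c(msgs, "symbols must not contain whitespace")
    if (anyDuplicated(s))
        msgs <- c(msgs, "symbols must be deduplicated")
    if (any(s != toupper(s)))
        msgs <- c(msgs, "symbols must be uppercased")
    if (length(msgs)) msgs else TRUE
})

#' InteractionNetwork: a simple undirected graph over gene symbols
#'
#' Nodes are uppercase gene symbols; edges are unordered symbol pairs stored
#' in canonical form (first endpoint lexicographically smaller). The graph is
#' simple: no self-loops, no duplicate edges, every endpoint is a node.
#'
#' @slot name single character label.
#' @slot nodes sorted character vector of node symbols.
#' @slot edges two-column character matrix of canonical edges.
#' @export
setClass("InteractionNetwork",
    representation(name = "character", nodes = "character",
                   edges = "matrix"),
    prototype(name = NA_character_, nodes = character(0),
              edges = matrix(character(0), ncol = 2)))

setValidity("InteractionNetwork", function(object) {
    msgs <- character(0)
    e <- object@edges
    n <- object@nodes
    if (!is.character(e) || ncol(e) != 2L)
        msgs <- c(msgs, "'edges' must be a two-column character matrix")
    if (anyDuplicated(n))
        msgs <- c(msgs, "duplicate node symbols")
    if (is.unsorted(n))
        msgs <- c(msgs, "nodes must be sorted")
    if (is.character(e) && ncol(e) == 2L && nrow(e) > 0L) {
        if (any(e[, 1L] == e[, 2L]))
            msgs <- c(msgs, "self-loops are not allowed")
        if (any(e[, 1L] > e[, 2L]))
            msgs <- c(msgs, "edges must be canonical (first endpoint smaller)")
        key <- paste(e[, 1L], e[, 2L], sep = "\r")
        if (anyDuplicated(key))
            msgs <- c(msgs, "duplicate edges")
        if (!all(c(e) %in% n))
            msgs <- c(msgs, "edge endpoints must be nodes")
    }
    if (length(msgs)) msgs else TRUE
})

#' SeededNetwork: a seed-directed neighborhood subnetwork
#'
#' An \linkS4class{InteractionNetwork} obtained by taking a set of seed genes
#' together with their direct interactors in a base network and keeping all
#' induced edges. Inherits every network operation.
#'
#' @slot seedsUsed the \linkS4class{GeneSet} of seeds actually present in the
#'   base network.
#' @slot baseName label of the base network the neighborhood was cut from.
#' @export
setClass("SeededNetwork",
    contains = "InteractionNetwork",
    representation(seedsUsed = "GeneSet", baseName = "character"),
    prototype(baseName = NA_character_))

setValidity("SeededNetwork", function(object) {
    if (!all(object@seedsUsed@symbols %in% object@nodes))
        "all used seeds must be nodes of the subnetwork"
    else TRUE
})

#' McodeParams: parameters of the MCODE module-detection procedure
#'
#' Defaults are the standard defaults of the MCODE method: loops excluded,
#' degree cutoff 2, node score cutoff 0.2, k-core filter 2, haircut on,
#' fluff off (density cutoff 0.1), maximum expansion depth 100.
#'
#' @slot includeLoops logical; self-loops are always dropped at network load,
#'   the flag is retained for fidelity to the reference parameter set.
#' @slot degreeCutoff integer; vertices below this degree get weight 0.
#' @slot nodeScoreCutoff numeric in [0,1]; expansion admits neighbors with
#'   weight > seed weight * (1 - nodeScoreCutoff).
#' @slot kCore integer; candidate complexes must contain a k-core of this k.
#' @slot haircut logical; iteratively strip singly connected module vertices.
#' @slot fluff logical; add boundary vertices with dense closed neighborhoods.
#' @slot fluffDensityCutoff numeric; density threshold for fluffing.
#' @slot maxDepth integer; breadth-first expansion depth limit from the seed.
#' @export
setClass("McodeParams",
    representation(includeLoops = "logical", degreeCutoff = "integer",
                   nodeScoreCutoff = "numeric", kCore = "integer",
                   haircut = "logical", fluff = "logical",
                   fluffDensityCutoff = "numeric", maxDepth = "integer"),
    prototype(includeLoops = FALSE, degreeCutoff = 2L,
              nodeScoreCutoff = 0.2, kCore = 2L, haircut = TRUE,
              fluff = FALSE, fluffDensityCutoff = 0.1, maxDepth = 100L))

setValidity("McodeParams", function(object) {
    msgs <- character(0)
    if (object@degreeCutoff < 0L) msgs <- c(msgs, "degreeCutoff must be >= 0")
    if (object@nodeScoreCutoff < 0 || object@nodeScoreCutoff > 1)
        msgs <- c(msgs, "nodeScoreCutoff must be in [0,1]")
    if (object@kCore < 1L) msgs <- c(msgs, "kCore must be >= 1")
    if (object@maxDepth < 1L) msgs <- c(msgs, "maxDepth must be >= 1")
    if (object@fluffDensityCutoff < 0)
        msgs <- c(msgs, "fluffDensityCutoff must be >= 0")
    if (length(msgs)) msgs else TRUE
})

#' Module: one densely connected region found by MCODE
#'
#' @slot members character vector of member gene symbols (sorted).
#' @slot score numeric; module density times member count.
#' @slot rank integer rank within its \linkS4class{ModuleSet}.
#' @export
setClass("Module",
    representation(members = "character", score = "numeric",
                   rank = "integer"),
    prototype(rank = NA_integer_))

setValidity("Module", function(object) {
    if (length(object@members) < 2L)
        "a module must have at least 2 members"
    else if (is.unsorted(object@members))
        "members must be sorted"
    else TRUE
})

#' ModuleSet: ordered MCODE output with the parameters used
#'
#' @slot modules list of \linkS4class{Module}.
#' @slot params the \linkS4class{McodeParams} used.
#' @slot network label of the source network.
#' @slot ordering either "score" (tool default) or "size" (node-count
#'   ranking as used for module extraction).
#' @export
setClass("ModuleSet",
    representation(modules = "list", params = "McodeParams",
                   network = "character", ordering = "character"),
    prototype(modules = list(), network = NA_character_,
              ordering = "score"))

setValidity("ModuleSet", function(object) {
    if (!all(vapply(object@modules, is, logical(1), "Module")))
        "all elements of 'modules' must be Module objects"
    else TRUE
})

#' GeneSetCollection: named gene sets read from a GMT file
#'
#' @slot name collection label.
#' @slot sets named list of character vectors (uppercased, deduplicated).
#' @slot universe optional explicit background gene set (character, possibly
#'   empty meaning "unspecified").
#' @export
setClass("GeneSetCollection",
    representation(name = "character", sets = "list",
                   universe = "character"),
    prototype(name = NA_character_, sets = list(),
              universe = character(0)))

setValidity("GeneSetCollection", function(object) {
    msgs <- character(0)
    if (length(object@sets)) {
        if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
            msgs <- c(msgs, "term names must be unique and non-NULL")
        if (any(vapply(object@sets, length, integer(1)) == 0L))
            msgs <- c(msgs, "gene sets must be non-empty")
    }
    if (length(msgs)) msgs else TRUE
})

#' ExpressionData: a gene-by-sample expression matrix with group labels
#'
#' Extends \link[SummarizedExperiment]{SummarizedExperiment}: one assay
#' named \code{"exprs"}, rownames are gene (or probe) symbols, and
#' \code{colData(x)$group} labels each sample \code{"disease"} or
#' \code{"control"}.
#'
#' @export
#' @import SummarizedExperiment
setClass("ExpressionData", contains = "SummarizedExperiment")

setValidity("ExpressionData", function(object) {
    msgs <- character(0)
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msgs <- c(msgs, "must contain an assay named 'exprs'")
    cd <- SummarizedExperiment::colData(object)
    if (!"group" %in% colnames(cd))
        msgs <- c(msgs, "colData must contain a 'group' column")
    else if (!all(cd$group %in% c("disease", "control")))
        msgs <- c(msgs, "group labels must be 'disease' or 'control'")
    if (is.null(rownames(object)))
        msgs <- c(msgs, "rownames (gene/probe symbols) are required")
    if (length(msgs)) msgs else TRUE
})
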