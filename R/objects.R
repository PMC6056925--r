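## Constructors, accessors and show methods for the core S4 objects.

#' Construct a GeneSet
#'
#' Normalizes symbols (uppercase, whitespace-trimmed, deduplicated, empties
#' dropped) and records provenance.
#'
#' @param symbols character vector of gene symbols.
#' @param name label for the set.
#' @param provenance free-text source descriptor.
#' @return a \linkS4class{GeneSet}.
#' @examples
#' GeneSet(c("tp53", "TP53", "brca1"), name = "demo")
#' @export
GeneSet <- function(symbols, name = "gene_set", provenance = "") {
    s <- toupper(trimws(as.character(symbols)))
    s <- s[!is.na(s) & nzchar(s)]
    s <- unique(s)
    new("GeneSet", name = name, symbols = s, provenance = provenance)
}

#' @rdname GeneSet-class
#' @aliases symbols,GeneSet-method
#' @export
setMethod("symbols", "GeneSet", function(x) x@symbols)

#' @rdname GeneSet-class
#' @aliases provenance,GeneSet-method
#' @export
setMethod("provenance", "GeneSet", function(x) x@provenance)

#' @rdname GeneSet-class
#' @aliases length,GeneSet-method
#' @param x a GeneSet.
#' @export
setMethod("length", "GeneSet", function(x) length(x@symbols))

setMethod("show", "GeneSet", function(object) {
    cat("GeneSet '", object@name, "': ", length(object@symbols),
        " symbols\n", sep = "")
    if (nzchar(object@provenance))
        cat("  provenance: ", object@provenance, "\n", sep = "")
    preview <- utils::head(object@symbols, 6L)
    if (length(preview))
        cat("  ", paste(preview, collapse = ", "),
            if (length(object@symbols) > 6L) ", ..." else "", "\n", sep = "")
})

## Canonicalize an edge table: uppercase, drop self-loops, order endpoints,
## deduplicate. Returns list(edges, nLoops, nDups).
canonicalizeEdges <- function(from, to) {
    from <- toupper(trimws(from))
    to <- toupper(trimws(to))
    loops <- from == to
    from2 <- pmin(from[!loops], to[!loops])
    to2 <- pmax(from[!loops], to[!loops])
    key <- paste(from2, to2, sep = "\r")
    dup <- duplicated(key)
    m <- cbind(from2[!dup], to2[!dup])
    if (nrow(m)) m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
    list(edges = m, nLoops = sum(loops), nDups = sum(dup))
}

#' Construct an InteractionNetwork
#'
#' Builds a simple undirected network from an edge table (and optionally
#' extra isolated nodes). Symbols are uppercased; self-loops and duplicate
#' (including reversed-duplicate) edges are dropped.
#'
#' @param from,to character vectors of edge endpoints (recycled pairwise).
#' @param nodes optional extra node symbols (isolated nodes allowed).
#' @param name network label.
#' @return an \linkS4class{InteractionNetwork}.
#' @examples
#' net <- InteractionNetwork(c("a", "b"), c("b", "c"), name = "toy")
#' nodes(net)
#' @export
InteractionNetwork <- function(from = character(0), to = character(0),
                               nodes = character(0), name = "network") {
    stopifnot(length(from) == length(to))
    can <- canonicalizeEdges(as.character(from), as.character(to))
    allNodes <- sort(unique(c(can$edges, toupper(trimws(as.character(nodes))))))
    allNodes <- allNodes[nzchar(allNodes)]
    new("InteractionNetwork", name = name, nodes = allNodes,
        edges = can$edges)
}

#' @rdname InteractionNetwork-class
#' @aliases nodes,InteractionNetwork-method
#' @export
setMethod("nodes", "InteractionNetwork", function(x) x@nodes)

#' @rdname InteractionNetwork-class
#' @aliases edges,InteractionNetwork-method
#' @export
setMethod("edges", "InteractionNetwork", function(x) {
    m <- x@edges
    colnames(m) <- c("from", "to")
    m
})

#' @rdname InteractionNetwork-class
#' @aliases nodeCount,InteractionNetwork-method
#' @export
setMethod("nodeCount", "InteractionNetwork", function(x) length(x@nodes))

#' @rdname InteractionNetwork-class
#' @aliases edgeCount,InteractionNetwork-method
#' @export
setMethod("edgeCount", "InteractionNetwork", function(x) nrow(x@edges))

setMethod("show", "InteractionNetwork", function(object) {
    cat(class(object), " '", object@name, "': ", length(object@nodes),
        " nodes, ", nrow(object@edges), " edges\n", sep = "")
})

setMethod("show", "SeededNetwork", function(object) {
    callNextMethod()
    cat("  seeded from '", object@baseName, "' with ",
        length(object@seedsUsed@symbols), " seeds\n", sep = "")
})

#' @rdname SeededNetwork-class
#' @aliases seedsUsed,SeededNetwork-method
#' @export
setMethod("seedsUsed", "SeededNetwork", function(x) x@seedsUsed)

## Named adjacency list (list of character vectors), computed once per call
## site; nodes with no neighbors map to character(0).
adjacencyList <- function(net) {
    adj <- vector("list", length(net@nodes))
    names(adj) <- net@nodes
    e <- net@edges
    if (nrow(e)) {
        nb <- split(c(e[, 2L], e[, 1L]), c(e[, 1L], e[, 2L]))
        adj[names(nb)] <- nb
    }
    adj[vapply(adj, is.null, logical(1))] <- list(character(0))
    adj
}

## igraph view of a network (vertex names preserved); used for standard
## topology statistics, not for module detection.
asIgraph <- function(net) {
    igraph::graph_from_data_frame(
        as.data.frame(edges(net), stringsAsFactors = FALSE),
        directed = FALSE,
        vertices = data.frame(name = net@nodes, stringsAsFactors = FALSE))
}

#' Construct MCODE parameters
#'
#' All arguments default to the standard MCODE defaults.
#'
#' @param includeLoops include self-loops (loops are removed at network load;
#'   kept for parameter-set fidelity).
#' @param degreeCutoff minimum degree for a vertex to receive a weight.
#' @param nodeScoreCutoff expansion threshold fraction in [0,1].
#' @param kCore minimum k-core a complex must contain.
#' @param haircut strip singly connected module vertices.
#' @param fluff add dense boundary vertices.
#' @param fluffDensityCutoff closed-neighborhood density threshold for fluff.
#' @param maxDepth breadth-first expansion depth limit.
#' @return a \linkS4class{McodeParams}.
#' @examples
#' mcodeParams()
#' mcodeParams(fluff = TRUE, fluffDensityCutoff = 0.2)
#' @export
mcodeParams <- function(includeLoops = FALSE, degreeCutoff = 2L,
                        nodeScoreCutoff = 0.2, kCore = 2L, haircut = TRUE,
                        fluff = FALSE, fluffDensityCutoff = 0.1,
                        maxDepth = 100L) {
    new("McodeParams", includeLoops = includeLoops,
        degreeCutoff = as.integer(degreeCutoff),
        nodeScoreCutoff = nodeScoreCutoff, kCore = as.integer(kCore),
        haircut = haircut, fluff = fluff,
        fluffDensityCutoff = fluffDensityCutoff,
        maxDepth = as.integer(maxDepth))
}

setMethod("show", "McodeParams", function(object) {
    cat("McodeParams: degreeCutoff=", object@degreeCutoff,
        ", nodeScoreCutoff=", object@nodeScoreCutoff,
        ", kCore=", object@kCore,
        ", haircut=", object@haircut,
        ", fluff=", object@fluff,
        " (densityCutoff=", object@fluffDensityCutoff, ")",
        ", maxDepth=", object@maxDepth, "\n", sep = "")
})

Module <- function(members, score, rank = NA_integer_) {
    new("Module", members = sort(members), score = score,
        rank = as.integer(rank))
}

#' @rdname Module-class
#' @aliases members,Module-method
#' @export
setMethod("members", "Module", function(x) x@members)

#' @rdname Module-class
#' @aliases moduleScore,Module-method
#' @export
setMethod("moduleScore", "Module", function(x) x@score)

setMethod("show", "Module", function(object) {
    cat("Module (rank ", object@rank, "): ", length(object@members),
        " members, score ", round(object@score, 3), "\n", sep = "")
})

#' @rdname ModuleSet-class
#' @aliases modules,ModuleSet-method
#' @export
setMethod("modules", "ModuleSet", function(x) x@modules)

#' @rdname ModuleSet-class
#' @aliases length,ModuleSet-method
#' @param x a ModuleSet.
#' @export
setMethod("length", "ModuleSet", function(x) length(x@modules))

#' @rdname ModuleSet-class
#' @aliases [[,ModuleSet-method
#' @param i index.
#' @export
setMethod("[[", "ModuleSet", function(x, i) x@modules[[i]])

setMethod("show", "ModuleSet", function(object) {
    cat("ModuleSet from '", object@network, "': ", length(object@modules),
        " modules (ordered by ", object@ordering, ")\n", sep = "")
    for (m in utils::head(object@modules, 5L))
        cat("  rank ", m@rank, ": ", length(m@members), " members, score ",
            round(m@score, 3), "\n", sep = "")
    if (length(object@modules) > 5L) cat("  ...\n")
})

#' @rdname GeneSetCollection-class
#' @aliases geneSets,GeneSetCollection-method
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname GeneSetCollection-class
#' @aliases length,GeneSetCollection-method
#' @param x a GeneSetCollection.
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

setMethod("show", "GeneSetCollection", function(object) {
    sizes <- vapply(object@sets, length, integer(1))
    cat("GeneSetCollection '", object@name, "': ", length(object@sets),
        " sets", sep = "")
    if (length(sizes))
        cat(" (sizes ", min(sizes), "-", max(sizes), ")", sep = "")
    cat("\n")
})

#' Construct an ExpressionData object
#'
#' @param values numeric gene-by-sample matrix with row and column names.
#' @param group character vector (or named vector keyed by sample) of
#'   \code{"disease"}/\code{"control"} labels, one per sample.
#' @return an \linkS4class{ExpressionData}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(c("A", "B", "C"), paste0("s", 1:4)))
#' ExpressionData(m, c("disease", "disease", "control", "control"))
#' @export
ExpressionData <- function(values, group) {
    values <- as.matrix(values)
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("expression matrix needs row (gene) and column (sample) names")
    if (!is.null(names(group)))
        group <- group[colnames(values)]
    group <- as.character(group)
    if (length(group) != ncol(values) || anyNA(group))
        stop("every sample needs a 'disease'/'control' group label")
    rownames(values) <- toupper(rownames(values))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values),
        colData = S4Vectors::DataFrame(group = group,
                                       row.names = colnames(values)))
    new("ExpressionData", se)
}

#' @rdname ExpressionData-class
#' @aliases exprValues,ExpressionData-method
#' @export
setMethod("exprValues", "ExpressionData", function(x)
    SummarizedExperiment::assay(x, "exprs"))

#' @rdname ExpressionData-class
#' @aliases sampleGroups,ExpressionData-method
#' @export
setMethod("sampleGroups", "ExpressionData", function(x) {
    g <- SummarizedExperiment::colData(x)$group
    names(g) <- colnames(x)
    g
})
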