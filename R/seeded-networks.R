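## Seed-directed neighborhood subnetworks and edge-retention reporting.
##
## The analysis builds two nested networks from a base PPI graph: the
## immune-or-disease-directed neighbor network (IOMDN; seeds = immune union
## disease genes, plus their direct interactors) and the disease-directed
## network (MGND; the same construction applied to the IOMDN with the
## disease genes as seeds).

#' Build a seed-directed neighbor network
#'
#' The node set is the seeds present in the base network plus every direct
#' neighbor of such a seed; the edge set is the full induced subgraph (edges
#' between two non-seed neighbors are kept). Seeds absent from the base are
#' reported via a message and retained in the returned \code{seedsUsed}
#' provenance only as a count.
#'
#' @param base an \linkS4class{InteractionNetwork}.
#' @param seeds a \linkS4class{GeneSet} (or character vector).
#' @param name label for the subnetwork.
#' @return a \linkS4class{SeededNetwork}.
#' @examples
#' base <- InteractionNetwork(c("A", "B", "C"), c("B", "C", "D"))
#' buildNeighborNetwork(base, GeneSet("A"), name = "nbhd")
#' @export
buildNeighborNetwork <- function(base, seeds, name = "seeded") {
    if (nodeCount(base) == 0L) stop("base network is empty")
    if (!is(seeds, "GeneSet")) seeds <- GeneSet(seeds, name = "seeds")
    present <- intersect(seeds@symbols, base@nodes)
    missing <- length(seeds@symbols) - length(present)
    if (length(present) == 0L)
        stop("none of the ", length(seeds@symbols),
             " seeds are present in network '", base@name, "'")
    if (missing > 0L)
        message("buildNeighborNetwork: ", missing, " of ",
                length(seeds@symbols), " seeds not found in '",
                base@name, "'")
    e <- base@edges
    touch <- e[, 1L] %in% present | e[, 2L] %in% present
    keepNodes <- sort(unique(c(present, c(e[touch, , drop = FALSE]))))
    induced <- e[e[, 1L] %in% keepNodes & e[, 2L] %in% keepNodes, ,
                 drop = FALSE]
    new("SeededNetwork", name = name, nodes = keepNodes, edges = induced,
        seedsUsed = GeneSet(present, name = seeds@name,
                            provenance = seeds@provenance),
        baseName = base@name)
}

#' Edge retention of a subnetwork within its base
#'
#' @param sub a \linkS4class{SeededNetwork} (or any network whose edges are
#'   a subset of the base's).
#' @param base the base \linkS4class{InteractionNetwork}.
#' @return list with \code{subEdges}, \code{baseEdges}, \code{fraction},
#'   and \code{percent} (the fraction rendered to 2 decimals).
#' @export
edgeRetention <- function(sub, base) {
    if (edgeCount(base) == 0L)
        stop("base network has no edges; retention fraction undefined")
    subKey <- paste(sub@edges[, 1L], sub@edges[, 2L], sep = "\r")
    baseKey <- paste(base@edges[, 1L], base@edges[, 2L], sep = "\r")
    if (!all(subKey %in% baseKey))
        stop("subnetwork contains edges absent from the base network")
    frac <- nrow(sub@edges) / nrow(base@edges)
    list(subEdges = nrow(sub@edges), baseEdges = nrow(base@edges),
         fraction = frac, percent = sprintf("%.2f%%", 100 * frac))
}
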