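## MCODE dense-module detection, implemented from scratch:
## vertex weighting by (highest k-core of the closed neighborhood) x
## (density of that core), greedy seeded expansion with a weight threshold,
## and k-core / haircut / fluff post-processing. Tie-breaks are
## lexicographic on gene symbol so output is fully deterministic.

## restrict an adjacency list to a node subset
subAdjacency <- function(adj, keep) {
    sub <- lapply(adj[keep], function(nb) nb[nb %in% keep])
    names(sub) <- keep
    sub
}

edgesWithin <- function(subadj) sum(lengths(subadj)) / 2

simpleDensity <- function(n, m) if (n < 2L) 0 else 2 * m / (n * (n - 1))

## peel vertices with internal degree < k until stable; returns surviving
## node names (possibly none)
peelToCore <- function(subadj, k) {
    repeat {
        deg <- lengths(subadj)
        drop <- names(deg)[deg < k]
        if (!length(drop) || !length(subadj)) break
        keep <- setdiff(names(subadj), drop)
        subadj <- subAdjacency(subadj, keep)
    }
    names(subadj)
}

## highest k-core of an adjacency list: largest k with a non-empty k-core
highestCore <- function(subadj) {
    if (!length(subadj)) return(list(k = 0L, nodes = character(0)))
    k <- 0L
    nodes <- names(subadj)
    repeat {
        nxt <- peelToCore(subadj, k + 1L)
        if (!length(nxt)) break
        k <- k + 1L
        nodes <- nxt
        subadj <- subAdjacency(subadj, nxt)
    }
    list(k = k, nodes = sort(nodes))
}

#' Highest k-core of a network
#'
#' The largest k such that a non-empty subgraph with minimum internal
#' degree >= k exists, found by iterative minimum-degree peeling, together
#' with that subgraph.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @return list with \code{k} (integer; 0 for an empty or edgeless graph
#'   of isolated nodes) and \code{core} (the induced
#'   \linkS4class{InteractionNetwork}).
#' @examples
#' tri <- InteractionNetwork(c("A", "A", "B"), c("B", "C", "C"))
#' highestKCore(tri)$k
#' @export
highestKCore <- function(net) {
    hc <- highestCore(adjacencyList(net))
    list(k = hc$k, core = inducedSubnetwork(net, hc$nodes,
                                            name = paste0(net@name, ".core")))
}

#' Induced subnetwork on a node subset
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param keep character vector of node symbols to keep.
#' @param name label.
#' @return an \linkS4class{InteractionNetwork} with all edges of \code{net}
#'   between kept nodes.
#' @export
inducedSubnetwork <- function(net, keep, name = net@name) {
    keep <- intersect(net@nodes, toupper(keep))
    e <- net@edges
    sel <- e[, 1L] %in% keep & e[, 2L] %in% keep
    new("InteractionNetwork", name = name, nodes = sort(keep),
        edges = e[sel, , drop = FALSE])
}

#' MCODE vertex weights
#'
#' For each vertex of degree >= \code{degreeCutoff}, the weight is the core
#' number k of the highest k-core of the vertex's closed neighborhood,
#' multiplied by that core's density. Other vertices get weight 0.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param params an \linkS4class{McodeParams}.
#' @return named numeric vector over all nodes.
#' @export
mcodeVertexWeights <- function(net, params = mcodeParams()) {
    adj <- adjacencyList(net)
    deg <- lengths(adj)
    w <- numeric(length(adj))
    names(w) <- names(adj)
    eligible <- names(adj)[deg >= params@degreeCutoff & deg > 0L]
    for (v in eligible) {
        nbhd <- c(v, adj[[v]])
        sub <- subAdjacency(adj, nbhd)
        hc <- highestCore(sub)
        if (hc$k > 0L) {
            core <- subAdjacency(sub, hc$nodes)
            w[v] <- hc$k * simpleDensity(length(hc$nodes), edgesWithin(core))
        }
    }
    w
}

#' MCODE complex prediction and post-processing
#'
#' Repeatedly seeds from the highest-weight unvisited vertex (ties broken by
#' lexicographic symbol order) and expands breadth-first up to
#' \code{maxDepth}, admitting unvisited neighbors whose weight exceeds
#' seed weight * (1 - \code{nodeScoreCutoff}); admitted vertices are marked
#' visited. Candidates without a \code{kCore}-core are discarded; haircut
#' iteratively strips vertices with fewer than 2 intra-module connections;
#' fluff (off by default) adds unvisited boundary vertices whose
#' closed-neighborhood density exceeds \code{fluffDensityCutoff} (such
#' vertices may be shared between modules). Each surviving module is scored
#' density * size and the set is returned in decreasing score order.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param weights named weight vector from \code{\link{mcodeVertexWeights}};
#'   recomputed when \code{NULL}.
#' @param params an \linkS4class{McodeParams}.
#' @return a \linkS4class{ModuleSet} (ordering \code{"score"}).
#' @export
mcodeComplexes <- function(net, weights = NULL, params = mcodeParams()) {
    adj <- adjacencyList(net)
    if (is.null(weights)) weights <- mcodeVertexWeights(net, params)
    if (!all(names(adj) %in% names(weights)))
        stop("weights must cover all nodes")
    w <- weights[names(adj)]
    ord <- names(adj)[order(-w, names(adj))]
    visited <- structure(logical(length(adj)), names = names(adj))
    thresholdFactor <- 1 - params@nodeScoreCutoff
    out <- list()
    for (seed in ord) {
        if (visited[seed]) next
        threshold <- w[seed] * thresholdFactor
        membersL <- list(seed)
        visited[seed] <- TRUE
        frontier <- seed
        depth <- 0L
        while (length(frontier) && depth < params@maxDepth) {
            nxt <- character(0)
            for (v in frontier) {
                nb <- adj[[v]]
                add <- nb[!visited[nb] & w[nb] > threshold]
                if (length(add)) {
                    visited[add] <- TRUE
                    nxt <- c(nxt, add)
                }
            }
            membersL[[length(membersL) + 1L]] <- nxt
            frontier <- nxt
            depth <- depth + 1L
        }
        members <- unlist(membersL, use.names = FALSE)
        sub <- subAdjacency(adj, members)
        if (highestCore(sub)$k < params@kCore) next
        if (params@haircut) {
            members <- peelToCore(sub, 2L)
            sub <- subAdjacency(adj, members)
        }
        if (params@fluff && length(members)) {
            boundary <- setdiff(unique(unlist(adj[members],
                                              use.names = FALSE)), members)
            boundary <- boundary[!visited[boundary]]
            fluffIn <- character(0)
            for (u in boundary) {
                nbhd <- c(u, adj[[u]])
                nsub <- subAdjacency(adj, nbhd)
                if (simpleDensity(length(nbhd), edgesWithin(nsub)) >
                    params@fluffDensityCutoff)
                    fluffIn <- c(fluffIn, u)
            }
            members <- c(members, fluffIn)
            sub <- subAdjacency(adj, members)
        }
        if (length(members) < 2L) next
        score <- simpleDensity(length(members), edgesWithin(sub)) *
            length(members)
        out[[length(out) + 1L]] <- Module(members, score)
    }
    if (length(out)) {
        firstMember <- vapply(out, function(m) m@members[1L], character(1))
        scores <- vapply(out, function(m) m@score, numeric(1))
        o <- order(-scores, firstMember)
        out <- out[o]
        for (i in seq_along(out)) out[[i]]@rank <- i
    }
    new("ModuleSet", modules = out, params = params, network = net@name,
        ordering = "score")
}

#' Detect modules with MCODE
#'
#' Convenience wrapper: computes vertex weights and predicts complexes.
#'
#' @inheritParams mcodeComplexes
#' @return a \linkS4class{ModuleSet}.
#' @examples
#' net <- InteractionNetwork(c("A", "A", "A", "B", "B", "C"),
#'                           c("B", "C", "D", "C", "D", "D"))
#' detectModules(net)
#' @export
detectModules <- function(net, params = mcodeParams()) {
    mcodeComplexes(net, mcodeVertexWeights(net, params), params)
}

#' Rank modules by node count and keep the top n
#'
#' Sort key: member count descending, then score descending, then
#' lexicographically smallest member symbol. Ranks are reassigned 1..n.
#'
#' @param ms a \linkS4class{ModuleSet}.
#' @param n number of modules to keep.
#' @return a \linkS4class{ModuleSet} (ordering \code{"size"}).
#' @export
rankModules <- function(ms, n = 5L) {
    if (n < 1L) stop("'n' must be >= 1")
    mods <- ms@modules
    if (length(mods) < n)
        message("rankModules: only ", length(mods),
                " modules available (requested ", n, ")")
    if (length(mods)) {
        sizes <- vapply(mods, function(m) length(m@members), integer(1))
        scores <- vapply(mods, function(m) m@score, numeric(1))
        firstMember <- vapply(mods, function(m) m@members[1L], character(1))
        o <- order(-sizes, -scores, firstMember)
        mods <- utils::head(mods[o], n)
        for (i in seq_along(mods)) mods[[i]]@rank <- i
    }
    new("ModuleSet", modules = mods, params = ms@params,
        network = ms@network, ordering = "size")
}
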