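## Topology statistics: density, degree, clustering, degree-distribution
## power-law fit, and category-stratified hub analysis.

#' Node degrees
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @return named integer vector over all nodes (isolated nodes get 0).
#' @export
nodeDegrees <- function(net) {
    deg <- integer(length(net@nodes))
    names(deg) <- net@nodes
    e <- net@edges
    if (nrow(e)) {
        t1 <- table(factor(c(e[, 1L], e[, 2L]), levels = net@nodes))
        deg[] <- as.integer(t1)
    }
    deg
}

#' Summarize network topology
#'
#' Density is \eqn{2E / (N(N-1))}; mean degree is \eqn{2E / N}; mean
#' clustering averages local clustering coefficients over all nodes, with
#' nodes of degree < 2 contributing 0 (isolated nodes included in the mean).
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @return list with \code{nodeCount}, \code{edgeCount}, \code{density},
#'   \code{meanDegree}, \code{meanClustering}, and a \code{perNode}
#'   data frame (node, degree, clustering).
#' @examples
#' tri <- InteractionNetwork(c("A", "A", "B"), c("B", "C", "C"))
#' topologySummary(tri)$density
#' @export
topologySummary <- function(net) {
    n <- length(net@nodes)
    m <- nrow(net@edges)
    if (n < 2L) {
        warning("density undefined for networks with fewer than 2 nodes; ",
                "reporting 0")
        density <- 0
    } else {
        density <- 2 * m / (n * (n - 1))
    }
    deg <- nodeDegrees(net)
    clust <- rep(0, n)
    names(clust) <- net@nodes
    if (m > 0L && n > 0L) {
        g <- asIgraph(net)
        lc <- igraph::transitivity(g, type = "local",
                                   vids = igraph::V(g), isolates = "zero")
        clust[igraph::V(g)$name] <- lc
    }
    list(nodeCount = n, edgeCount = m, density = density,
         meanDegree = if (n > 0L) 2 * m / n else 0,
         meanClustering = if (n > 0L) mean(clust) else 0,
         perNode = data.frame(node = net@nodes, degree = as.integer(deg),
                              clustering = as.numeric(clust),
                              stringsAsFactors = FALSE))
}

#' Degree distribution with a descriptive log-log power-law fit
#'
#' The histogram maps each occurring degree k to its node count N(k). The
#' fit is ordinary least squares of \eqn{\log_{10} N(k)} on
#' \eqn{\log_{10} k} over occupied bins with k >= 1; with fewer than two
#' such bins, slope and r-squared are \code{NA}.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @return list with \code{histogram} (data frame degree/count),
#'   \code{loglogSlope}, \code{loglogR2}.
#' @export
degreeDistribution <- function(net) {
    deg <- nodeDegrees(net)
    tab <- table(deg)
    hist <- data.frame(degree = as.integer(names(tab)),
                       count = as.integer(tab))
    fitRows <- hist$degree >= 1L & hist$count > 0L
    slope <- NA_real_; r2 <- NA_real_
    if (sum(fitRows) >= 2L) {
        x <- log10(hist$degree[fitRows])
        y <- log10(hist$count[fitRows])
        fit <- stats::lm(y ~ x)
        slope <- unname(stats::coef(fit)[2L])
        tss <- sum((y - mean(y))^2)
        ## r^2 computed directly; exact fits would make summary.lm warn
        r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 1
    }
    list(histogram = hist, loglogSlope = slope, loglogR2 = r2)
}

#' Category-stratified degree report and top hubs
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param cmap named factor covering all nodes
#'   (see \code{\link{classifyNodes}}).
#' @param k number of top hubs to report; ties in degree are broken by
#'   lexicographic symbol order.
#' @return list with \code{meanDegree} (named numeric per category; NaN for
#'   empty categories) and \code{topHubs} (data frame symbol, degree,
#'   category).
#' @export
hubAnalysis <- function(net, cmap, k = 5L) {
    if (k <= 0L) stop("'k' must be a positive integer")
    if (!all(net@nodes %in% names(cmap)))
        stop("category map must cover all network nodes")
    deg <- nodeDegrees(net)
    cat <- factor(cmap[net@nodes], levels = NODE_CATEGORIES)
    meanDeg <- vapply(NODE_CATEGORIES, function(cc)
        mean(deg[cat == cc]), numeric(1))
    ord <- order(-deg, names(deg))
    top <- utils::head(ord, k)
    list(meanDegree = meanDeg,
         topHubs = data.frame(symbol = names(deg)[top],
                              degree = as.integer(deg[top]),
                              category = as.character(cat[top]),
                              stringsAsFactors = FALSE))
}
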