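## Independent brute-force oracles used across the suite. These never call
## the code paths they check.

edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

## random simple graph over nNodes symbols with nDraw random pairs
randomNet <- function(nNodes, nDraw, name = "rand") {
    syms <- sprintf("V%02d", seq_len(nNodes))
    a <- sample(syms, nDraw, replace = TRUE)
    b <- sample(syms, nDraw, replace = TRUE)
    InteractionNetwork(a, b, nodes = syms, name = name)
}

## exhaustive pair/triple-counting topology statistics
bfTopology <- function(net) {
    ns <- nodes(net)
    e <- edges(net)
    keys <- edgeKey(e[, 1], e[, 2])
    hasEdge <- function(a, b) edgeKey(a, b) %in% keys
    deg <- vapply(ns, function(v)
        sum(e[, 1] == v) + sum(e[, 2] == v), numeric(1))
    clust <- vapply(ns, function(v) {
        nb <- unique(c(e[e[, 1] == v, 2], e[e[, 2] == v, 1]))
        d <- length(nb)
        if (d < 2) return(0)
        cnt <- 0
        for (i in seq_len(d - 1)) for (j in (i + 1):d)
            if (hasEdge(nb[i], nb[j])) cnt <- cnt + 1
        2 * cnt / (d * (d - 1))
    }, numeric(1))
    n <- length(ns)
    list(density = if (n < 2) 0 else 2 * nrow(e) / (n * (n - 1)),
         meanDegree = if (n > 0) 2 * nrow(e) / n else 0,
         meanClustering = if (n > 0) mean(clust) else 0,
         degree = deg, clustering = clust)
}

## exhaustive highest-k-core value: max over all non-empty subsets of the
## minimum internal degree (feasible for <= 12 nodes)
bfHighestCoreK <- function(net) {
    ns <- nodes(net)
    e <- edges(net)
    keys <- edgeKey(e[, 1], e[, 2])
    best <- 0L
    n <- length(ns)
    if (n == 0) return(0L)
    for (mask in seq_len(2^n - 1)) {
        sub <- ns[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
        if (length(sub) <= best) next
        mind <- min(vapply(sub, function(v)
            sum(edgeKey(v, setdiff(sub, v)) %in% keys), numeric(1)))
        if (mind > best) best <- as.integer(mind)
    }
    best
}

## hypergeometric upper tail by exhaustive enumeration of all draws
bfHyper <- function(N, K, n, k) {
    bg <- seq_len(N)
    term <- seq_len(K)
    draws <- utils::combn(N, n)
    mean(apply(draws, 2, function(d) sum(d %in% term) >= k))
}

## naive sum-based Pearson correlation
bfPearson <- function(x, y) {
    n <- length(x)
    num <- sum(x * y) - n * mean(x) * mean(y)
    den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
    num / den
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
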