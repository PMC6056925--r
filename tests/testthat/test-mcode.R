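makeClique <- function(syms) {
    p <- t(utils::combn(syms, 2))
    list(from = p[, 1], to = p[, 2])
}

test_that("highest k-core matches hand peeling and exhaustive search", {
    tri <- InteractionNetwork(c("A", "A", "B"), c("B", "C", "C"))
    hk <- highestKCore(tri)
    expect_equal(hk$k, 2L)
    expect_setequal(nodes(hk$core), c("A", "B", "C"))
    star <- InteractionNetwork(rep("C", 5), paste0("L", 1:5))
    hs <- highestKCore(star)
    expect_equal(hs$k, 1L)
    expect_equal(nodeCount(hs$core), 6L)
    ## K4 plus a pendant vertex: the K4 is the 3-core
    k4 <- makeClique(c("A", "B", "C", "D"))
    net <- InteractionNetwork(c(k4$from, "D"), c(k4$to, "E"))
    hp <- highestKCore(net)
    expect_equal(hp$k, 3L)
    expect_setequal(nodes(hp$core), c("A", "B", "C", "D"))
    expect_equal(highestKCore(InteractionNetwork())$k, 0L)
    ## exhaustive-subset oracle on random graphs (<= 10 nodes)
    set.seed(77)
    for (rep in 1:5) {
        rnet <- randomNet(sample(4:10, 1), sample(4:20, 1))
        expect_equal(highestKCore(rnet)$k, bfHighestCoreK(rnet))
    }
})

test_that("highest k-core agrees with igraph coreness", {
    set.seed(78)
    for (rep in 1:5) {
        net <- randomNet(30, 60)
        g <- igraph::graph_from_edgelist(unname(edges(net)),
                                         directed = FALSE)
        expect_equal(highestKCore(net)$k, max(igraph::coreness(g)))
    }
})

test_that("vertex weights follow the core-density formula", {
    k4 <- makeClique(c("A", "B", "C", "D"))
    net <- InteractionNetwork(k4$from, k4$to)
    w <- mcodeVertexWeights(net)
    expect_equal(unname(w), rep(3, 4))  # 3-core of density 1
    star <- InteractionNetwork(rep("C", 5), paste0("L", 1:5))
    ws <- mcodeVertexWeights(star)
    expect_equal(unname(ws["C"]), 1 / 3, tolerance = 1e-12)  # 1 * 5/15
    expect_equal(unname(ws[paste0("L", 1:5)]), rep(0, 5))  # below cutoff
})

test_that("complex prediction recovers disjoint cliques with exact scores", {
    k5 <- makeClique(paste0("A", 1:5))
    k3 <- makeClique(paste0("X", 1:3))
    net <- InteractionNetwork(c(k5$from, k3$from), c(k5$to, k3$to))
    ms <- detectModules(net)
    expect_equal(length(ms), 2L)
    expect_setequal(members(ms[[1]]), paste0("A", 1:5))
    expect_equal(moduleScore(ms[[1]]), 5)
    expect_setequal(members(ms[[2]]), paste0("X", 1:3))
    expect_equal(moduleScore(ms[[2]]), 3)
})

test_that("a pure cycle is absorbed into a single 2-core module", {
    ## hand simulation: every vertex weight 1 * 2/3; expansion threshold
    ## 0.8 * 2/3 < 2/3 admits every neighbor, so the whole cycle becomes
    ## one candidate; the cycle is itself a 2-core and survives haircut
    syms <- sprintf("N%02d", 1:20)
    cyc <- InteractionNetwork(syms, syms[c(2:20, 1)])
    ms <- detectModules(cyc)
    expect_equal(length(ms), 1L)
    expect_setequal(members(ms[[1]]), syms)
    expect_equal(moduleScore(ms[[1]]), (2 * 20 / (20 * 19)) * 20,
                 tolerance = 1e-12)
})

test_that("modules are disjoint, contain a 2-core, and are order-invariant", {
    sim <- simulateNetwork(scenarioConfig(), seed = 21)
    ms <- detectModules(sim$network)
    allMembers <- unlist(lapply(modules(ms), members))
    expect_equal(anyDuplicated(allMembers), 0L)
    for (m in modules(ms)) {
        core <- highestKCore(inducedSubnetwork(sim$network, members(m)))
        expect_true(core$k >= 2L)
    }
    ## rebuilding the same graph from permuted edge input changes nothing
    e <- edges(sim$network)
    perm <- sample(nrow(e))
    flip <- sample(c(TRUE, FALSE), nrow(e), replace = TRUE)
    from2 <- ifelse(flip, e[, 2], e[, 1])[perm]
    to2 <- ifelse(flip, e[, 1], e[, 2])[perm]
    net2 <- InteractionNetwork(from2, to2, nodes = sample(nodes(sim$network)),
                               name = sim$network@name)
    ms2 <- detectModules(net2)
    expect_equal(lapply(modules(ms2), members),
                 lapply(modules(ms), members))
    expect_equal(vapply(modules(ms2), moduleScore, numeric(1)),
                 vapply(modules(ms), moduleScore, numeric(1)))
})

test_that("planted dense modules are recovered on average across seeds", {
    ## per-replicate overlap fluctuates (the expansion threshold trims
    ## weakly connected members), so the stable statement is the mean
    ## Jaccard of the top-scoring module over replicates
    js <- vapply(1:6, function(i) {
        sim <- simulateNetwork(scenarioConfig(), seed = 1000 + i)
        truth <- sim$truth$plantedModules[[1]]$members
        jaccard(members(detectModules(sim$network)[[1]]), truth)
    }, numeric(1))
    expect_gte(mean(js), 0.8)
    expect_true(all(js > 0.5))
})

test_that("module ranking sorts by size, then score, then first member", {
    mods <- list()
    mk <- function(members, score) new("Module", members = sort(members),
                                       score = score, rank = NA_integer_)
    ms <- new("ModuleSet",
              modules = list(mk(paste0("C", 1:5), 3.5),
                             mk(paste0("A", 1:7), 2.0),
                             mk(paste0("B", 1:5), 4.0),
                             mk(paste0("D", 1:3), 1.0)),
              params = mcodeParams(), network = "toy", ordering = "score")
    top <- rankModules(ms, 4)
    expect_equal(vapply(modules(top), function(m) length(members(m)),
                        integer(1)), c(7L, 5L, 5L, 3L))
    expect_equal(members(top[[2]])[1], "B1")  # score 4.0 before 3.5
    expect_equal(vapply(modules(top), function(m) m@rank, integer(1)), 1:4)
    ## n beyond the available module count returns everything
    expect_message(all4 <- rankModules(ms, 10), "only 4 modules")
    expect_equal(length(all4), 4L)
    ## random ordering oracle
    set.seed(88)
    rmods <- lapply(1:20, function(i)
        mk(sprintf("M%02d_%02d", i, seq_len(sample(3:9, 1))),
           round(stats::runif(1), 3)))
    msr <- new("ModuleSet", modules = rmods, params = mcodeParams(),
               network = "toy", ordering = "score")
    got <- rankModules(msr, 20)
    sizes <- vapply(rmods, function(m) length(members(m)), integer(1))
    scores <- vapply(rmods, function(m) moduleScore(m), numeric(1))
    firsts <- vapply(rmods, function(m) members(m)[1], character(1))
    want <- rmods[order(-sizes, -scores, firsts)]
    expect_equal(lapply(modules(got), members), lapply(want, members))
})
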