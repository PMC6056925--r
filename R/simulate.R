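## Synthetic benchmark generator: scale-free interaction background with
## planted dense modules overlapping the seed sets, and a latent-factor
## expression model with planted edge co-expression and mean-shift
## differential expression. Every draw is governed by an explicit seed and
## full ground truth is returned for recovery tests.

#' Scenario configuration for the synthetic-data generator
#'
#' Defaults describe the benchmark conditions used throughout the package:
#' a 500-node preferential-attachment background with 2 edges per arriving
#' node, one planted 12-node module of internal density 0.9, 21 disease and
#' 18 control samples, planted edge correlations of magnitude 0.7 (a
#' quarter negative), and differential-expression effect d = 1.5.
#'
#' @param nBackground background node count.
#' @param mAttach edges added per arriving node (preferential attachment).
#' @param modules list of module specs, each \code{list(size=, density=)}.
#' @param diseaseSize,immuneSize seed-set sizes.
#' @param moduleDiseaseSeeds,moduleImmuneSeeds how many members of each
#'   planted module are assigned to the disease / immune seed set.
#' @param diseaseAlsoImmuneFraction fraction of disease seeds that are also
#'   immune seeds (produces the BOTH category).
#' @param nDisease,nControl sample sizes per group.
#' @param rho magnitude of the implied correlation on planted module edges.
#' @param negativeFraction fraction of module genes with negative factor
#'   loadings (yields negative planted correlations).
#' @param noiseSd residual standard deviation of the expression model.
#' @param deEffect standardized mean-shift d for planted DE genes.
#' @param moduleDeFraction fraction of module members planted as DE.
#' @param backgroundDeCount additional background genes planted as DE.
#' @param upFraction fraction of planted DE genes shifted upward in disease.
#' @return a validated configuration list (class \code{ScenarioConfig}).
#' @export
scenarioConfig <- function(nBackground = 500L, mAttach = 2L,
                           modules = list(list(size = 12L, density = 0.9)),
                           diseaseSize = 15L, immuneSize = 60L,
                           moduleDiseaseSeeds = 3L, moduleImmuneSeeds = 6L,
                           diseaseAlsoImmuneFraction = 0.5,
                           nDisease = 21L, nControl = 18L,
                           rho = 0.7, negativeFraction = 0.25,
                           noiseSd = 1, deEffect = 1.5,
                           moduleDeFraction = 0.5, backgroundDeCount = 20L,
                           upFraction = 0.5) {
    cfg <- list(nBackground = as.integer(nBackground),
                mAttach = as.integer(mAttach), modules = modules,
                diseaseSize = as.integer(diseaseSize),
                immuneSize = as.integer(immuneSize),
                moduleDiseaseSeeds = as.integer(moduleDiseaseSeeds),
                moduleImmuneSeeds = as.integer(moduleImmuneSeeds),
                diseaseAlsoImmuneFraction = diseaseAlsoImmuneFraction,
                nDisease = as.integer(nDisease),
                nControl = as.integer(nControl),
                rho = rho, negativeFraction = negativeFraction,
                noiseSd = noiseSd, deEffect = deEffect,
                moduleDeFraction = moduleDeFraction,
                backgroundDeCount = as.integer(backgroundDeCount),
                upFraction = upFraction)
    stopifnot(cfg$nBackground > 0L, cfg$mAttach > 0L,
              cfg$nDisease >= 4L, cfg$nControl >= 4L,
              abs(cfg$rho) < 1, cfg$noiseSd > 0, cfg$deEffect >= 0)
    for (m in cfg$modules) {
        if (m$size > cfg$nBackground)
            stop("planted module size exceeds background node count")
        if (m$density <= 0 || m$density > 1)
            stop("planted module density must be in (0, 1]")
    }
    class(cfg) <- "ScenarioConfig"
    cfg
}

#' Simulate a scale-free network with planted dense modules
#'
#' Preferential-attachment background; each planted module is realized by
#' adding edges among a sampled member set until its internal density
#' reaches the target. Disease and immune seeds are assigned so that seeds
#' are enriched inside the planted modules. Fully deterministic given the
#' seed.
#'
#' @param cfg a \code{\link{scenarioConfig}}.
#' @param seed integer RNG seed.
#' @return list with \code{network} (an \linkS4class{InteractionNetwork})
#'   and \code{truth} (planted modules, seed assignment, config, seed).
#' @export
simulateNetwork <- function(cfg = scenarioConfig(), seed = 1L) {
    set.seed(seed)
    n <- cfg$nBackground
    g <- igraph::sample_pa(n, power = 1, m = cfg$mAttach,
                           directed = FALSE)
    syms <- sprintf("G%0*d", nchar(as.character(n)), seq_len(n))
    el <- igraph::as_edgelist(g, names = FALSE)
    from <- syms[el[, 1L]]; to <- syms[el[, 2L]]
    available <- syms
    plantedModules <- list()
    for (mi in seq_along(cfg$modules)) {
        modSpec <- cfg$modules[[mi]]
        memb <- sort(sample(available, modSpec$size))
        available <- setdiff(available, memb)
        pairs <- t(utils::combn(memb, 2L))
        have <- paste(pmin(from, to), pmax(from, to), sep = "\r")
        pkey <- paste(pairs[, 1L], pairs[, 2L], sep = "\r")
        present <- pkey %in% have
        needed <- ceiling(modSpec$density * nrow(pairs)) - sum(present)
        if (needed > 0L) {
            missingIdx <- which(!present)
            addIdx <- missingIdx[sample.int(length(missingIdx), needed)]
            from <- c(from, pairs[addIdx, 1L])
            to <- c(to, pairs[addIdx, 2L])
        }
        plantedModules[[mi]] <- list(members = memb,
                                     targetDensity = modSpec$density)
    }
    net <- InteractionNetwork(from, to, nodes = syms, name = "synthetic")
    ## seed assignment: module members first, then background fill
    moduleMembers <- lapply(plantedModules, `[[`, "members")
    disease <- character(0); immune <- character(0)
    for (memb in moduleMembers) {
        dPick <- sample(memb, min(cfg$moduleDiseaseSeeds, length(memb)))
        rest <- setdiff(memb, dPick)
        iPick <- sample(rest, min(cfg$moduleImmuneSeeds, length(rest)))
        disease <- c(disease, dPick)
        immune <- c(immune, iPick)
    }
    bgPool <- setdiff(syms, unlist(moduleMembers))
    if (length(disease) < cfg$diseaseSize)
        disease <- c(disease,
                     sample(bgPool, cfg$diseaseSize - length(disease)))
    ## BOTH category: a fraction of disease seeds are also immune
    both <- sample(disease,
                   round(cfg$diseaseAlsoImmuneFraction * length(disease)))
    immune <- unique(c(immune, both))
    if (length(immune) < cfg$immuneSize)
        immune <- c(immune, sample(setdiff(bgPool, c(disease, immune)),
                                   cfg$immuneSize - length(immune)))
    truth <- list(plantedModules = plantedModules,
                  seedAssignment = list(immune = sort(immune),
                                        disease = sort(disease)),
                  correlatedEdges = NULL, deGenes = NULL,
                  config = unclass(cfg), seed = seed)
    list(network = net, truth = truth)
}

#' Simulate expression with planted co-expression and differential genes
#'
#' Per planted module s, a latent factor f_s is drawn per sample; a member
#' gene g gets mu_g + beta_g f_s + eps with eps ~ Normal(0, noiseSd^2), so
#' two members g, h have implied correlation
#' beta_g beta_h / sqrt((beta_g^2 + sigma^2)(beta_h^2 + sigma^2)); loadings
#' are sized so its magnitude equals \code{cfg$rho}, with signs drawn per
#' gene. Planted DE genes get d * (their total SD) added to (or subtracted
#' from) the disease samples. Non-module genes are independent noise.
#'
#' @param net network from \code{\link{simulateNetwork}}.
#' @param truth truth list from \code{\link{simulateNetwork}}.
#' @param cfg a \code{\link{scenarioConfig}}.
#' @param seed integer RNG seed.
#' @return list with \code{expression} (an \linkS4class{ExpressionData})
#'   and the completed \code{truth} (correlated edges, DE genes).
#' @export
simulateExpression <- function(net, truth, cfg = scenarioConfig(),
                               seed = 1L) {
    set.seed(seed)
    genes <- nodes(net)
    nS <- cfg$nDisease + cfg$nControl
    samples <- c(sprintf("D%02d", seq_len(cfg$nDisease)),
                 sprintf("C%02d", seq_len(cfg$nControl)))
    group <- rep(c("disease", "control"), c(cfg$nDisease, cfg$nControl))
    sigma <- cfg$noiseSd
    betaMag <- sigma * sqrt(abs(cfg$rho) / (1 - abs(cfg$rho)))
    mu <- stats::rnorm(length(genes), mean = 7, sd = 1)
    names(mu) <- genes
    vals <- matrix(stats::rnorm(length(genes) * nS, sd = sigma),
                   nrow = length(genes),
                   dimnames = list(genes, samples)) + mu
    loadings <- numeric(length(genes)); names(loadings) <- genes
    for (pm in truth$plantedModules) {
        f <- stats::rnorm(nS)
        signs <- ifelse(stats::runif(length(pm$members)) <
                        cfg$negativeFraction, -1, 1)
        beta <- betaMag * signs
        names(beta) <- pm$members
        loadings[pm$members] <- beta
        vals[pm$members, ] <- vals[pm$members, ] +
            outer(beta, f)
    }
    ## planted correlated edges: network edges internal to a module
    ce <- NULL
    for (pm in truth$plantedModules) {
        e <- net@edges
        sel <- e[, 1L] %in% pm$members & e[, 2L] %in% pm$members
        if (any(sel)) {
            em <- e[sel, , drop = FALSE]
            rhoSigned <- abs(cfg$rho) * sign(loadings[em[, 1L]]) *
                sign(loadings[em[, 2L]])
            ce <- rbind(ce, data.frame(from = em[, 1L], to = em[, 2L],
                                       rho = as.numeric(rhoSigned),
                                       stringsAsFactors = FALSE))
        }
    }
    ## planted DE genes: module members + background fill
    moduleMembers <- unlist(lapply(truth$plantedModules, `[[`, "members"))
    deGenes <- character(0)
    if (length(moduleMembers))
        deGenes <- sample(moduleMembers,
                          round(cfg$moduleDeFraction * length(moduleMembers)))
    bgPool <- setdiff(genes, moduleMembers)
    if (cfg$backgroundDeCount > 0L && length(bgPool))
        deGenes <- c(deGenes,
                     sample(bgPool, min(cfg$backgroundDeCount,
                                        length(bgPool))))
    de <- NULL
    if (length(deGenes)) {
        dirUp <- stats::runif(length(deGenes)) < cfg$upFraction
        sigmaTotal <- sqrt(loadings[deGenes]^2 + sigma^2)
        shift <- cfg$deEffect * sigmaTotal * ifelse(dirUp, 1, -1)
        vals[deGenes, group == "disease"] <-
            vals[deGenes, group == "disease"] + shift
        de <- data.frame(gene = deGenes, d = cfg$deEffect,
                         direction = ifelse(dirUp, "up", "down"),
                         stringsAsFactors = FALSE)
        de <- de[order(de$gene), , drop = FALSE]
        rownames(de) <- NULL
    }
    truth$correlatedEdges <- ce
    truth$deGenes <- de
    list(expression = ExpressionData(vals, structure(group,
                                                     names = samples)),
         truth = truth)
}

#' Write a complete synthetic scenario bundle to disk
#'
#' Simulates a network and expression data and writes every input the
#' pipeline consumes: PPI edge list, immune and disease seed lists,
#' expression TSV plus sample labels, a GMT collection (the planted module
#' sets, a planted drug-target set drawn from module members, and decoy
#' sets), and the ground-truth JSON.
#'
#' @param cfg a \code{\link{scenarioConfig}}.
#' @param seed integer RNG seed (the expression draw uses seed + 1).
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the file paths and the in-memory objects.
#' @export
makeScenario <- function(cfg = scenarioConfig(), seed = 1L,
                         outDir = tempfile("scenario")) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    sim <- simulateNetwork(cfg, seed)
    exprSeed <- (seed %% (.Machine$integer.max - 1L)) + 1L
    ex <- simulateExpression(sim$network, sim$truth, cfg, exprSeed)
    truth <- ex$truth
    p <- function(f) file.path(outDir, f)
    writeNetwork(sim$network, p("ppi_edges.tsv"), "tsv-edge-list")
    writeLines(truth$seedAssignment$immune, p("immune_genes.txt"))
    writeLines(truth$seedAssignment$disease, p("disease_genes.txt"))
    v <- exprValues(ex$expression)
    utils::write.table(data.frame(gene = rownames(v), v,
                                  check.names = FALSE),
                       p("expression.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(data.frame(sample = colnames(v),
                                  group = sampleGroups(ex$expression)),
                       p("sample_labels.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    ## GMT: planted modules, a drug-target set from module members, decoys
    set.seed(exprSeed + 1L)
    sets <- list()
    for (i in seq_along(truth$plantedModules))
        sets[[paste0("planted_module_", i)]] <-
            truth$plantedModules[[i]]$members
    allMembers <- unlist(lapply(truth$plantedModules, `[[`, "members"))
    if (length(allMembers)) {
        drug <- sort(c(sample(allMembers,
                              max(3L, length(allMembers) %/% 2L)),
                       sample(setdiff(nodes(sim$network), allMembers), 3L)))
        sets[["planted_drug_target"]] <- drug
        truth$drugTargets <- drug
    }
    for (d in 1:3)
        sets[[paste0("decoy_set_", d)]] <-
            sort(sample(setdiff(nodes(sim$network), allMembers), 15L))
    writeGmt(sets, p("genesets.gmt"))
    jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(list(dir = outDir,
                   files = list(ppi = p("ppi_edges.tsv"),
                                immune = p("immune_genes.txt"),
                                disease = p("disease_genes.txt"),
                                expression = p("expression.tsv"),
                                labels = p("sample_labels.tsv"),
                                gmt = p("genesets.gmt"),
                                truth = p("truth.json")),
                   network = sim$network, expression = ex$expression,
                   truth = truth))
}
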