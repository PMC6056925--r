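## Full-analysis orchestration: seed catalogs -> seeded networks ->
## topology -> MCODE modules -> expression overlay -> enrichment, driven by
## one configuration (list, YAML or JSON), producing artifact files and a
## single machine-readable report.

#' Default pipeline configuration
#'
#' Every threshold the analysis uses appears explicitly so that runs are
#' self-documenting: co-expression alpha 0.05 with strong-correlation
#' cutoff 0.5, differential-expression alpha 0.05 (Welch), enrichment
#' alpha 0.01, and the top 5 modules by node count.
#'
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function() {
    list(scenario = unclass(scenarioConfig()),
         inputs = NULL,
         thresholds = list(coexprAlpha = 0.05, strongThreshold = 0.5,
                           deAlpha = 0.05, deVariant = "welch",
                           enrichAlpha = 0.01, topModules = 5L),
         seed = 1L)
}

readPipelineConfig <- function(config) {
    if (is.character(config) && length(config) == 1L) {
        if (!file.exists(config)) stop("config file not found: ", config)
        config <- if (grepl("\\.json$", config, ignore.case = TRUE))
            jsonlite::read_json(config, simplifyVector = TRUE)
        else yaml::read_yaml(config)
    }
    base <- defaultPipelineConfig()
    if (!is.null(config$thresholds))
        base$thresholds <- utils::modifyList(base$thresholds,
                                             config$thresholds)
    if (!is.null(config$inputs)) {
        base$inputs <- config$inputs
        base$scenario <- config$scenario # NULL unless both given
    } else if (!is.null(config$scenario)) {
        sc <- unclass(scenarioConfig())
        base$scenario <- utils::modifyList(sc, config$scenario)
    }
    if (!is.null(config$seed)) base$seed <- config$seed
    base
}

stageLog <- function(...) message("[", format(Sys.time(), "%H:%M:%S"),
                                  "] ", ...)

#' Run the full seeded-network analysis pipeline
#'
#' Stages: input loading (or synthetic-scenario generation), construction
#' of the immune-or-disease-directed neighbor network (IOMDN) and the
#' disease-directed network (MGND) nested inside it, node classification
#' and tallies, topology summaries and degree-distribution fits, edge
#' retention, MCODE module detection with node-count ranking, expression
#' overlay (edge co-expression on disease samples, differential
#' expression, per-module reports), and hypergeometric over-representation
#' of the top-module genes. Stages without inputs (no expression, no gene
#' sets) are skipped and their report sections omitted.
#'
#' @param config configuration list, or path to a YAML/JSON file. See
#'   \code{\link{defaultPipelineConfig}}; supply \code{inputs} (paths
#'   \code{ppi}, \code{immune}, \code{disease}, and optionally
#'   \code{expression} + \code{labels} and \code{gmt}, with optional
#'   \code{*Dialect} entries) or a \code{scenario} block for synthetic
#'   data.
#' @param outDir directory for artifact files and \code{report.json}.
#' @param seed integer seed overriding the config's.
#' @return the report, invisibly (also written to
#'   \code{file.path(outDir, "report.json")}).
#' @export
runPipeline <- function(config = defaultPipelineConfig(),
                        outDir = tempfile("mgnet"), seed = NULL) {
    cfg <- readPipelineConfig(config)
    if (!is.null(seed)) cfg$seed <- seed
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    th <- cfg$thresholds
    truth <- NULL
    if (!is.null(cfg$inputs)) {
        ins <- cfg$inputs
        for (need in c("ppi", "immune", "disease"))
            if (is.null(ins[[need]]))
                stop("config error: inputs$", need, " is required")
        stageLog("loading inputs")
        ppi <- readNetwork(ins$ppi,
                           dialect = ins$ppiDialect %||% "tsv-edge-list",
                           name = "PPI")
        immune <- readGeneSet(ins$immune,
                              dialect = ins$immuneDialect %||% "plain-list",
                              name = "immune")
        disease <- readGeneSet(ins$disease,
                               dialect = ins$diseaseDialect %||%
                                   "plain-list",
                               name = "disease")
        expr <- NULL
        if (!is.null(ins$expression))
            expr <- readExpression(ins$expression,
                                   dialect = ins$expressionDialect %||%
                                       "plain-tsv",
                                   labels = ins$labels)
        coll <- if (!is.null(ins$gmt)) readGmt(ins$gmt) else NULL
    } else {
        stageLog("simulating synthetic scenario (seed ", cfg$seed, ")")
        sc <- do.call(scenarioConfig, cfg$scenario)
        bundle <- makeScenario(sc, seed = cfg$seed, outDir = outDir)
        truth <- bundle$truth
        ppi <- bundle$network
        immune <- GeneSet(truth$seedAssignment$immune, name = "immune",
                          provenance = "synthetic scenario")
        disease <- GeneSet(truth$seedAssignment$disease, name = "disease",
                           provenance = "synthetic scenario")
        expr <- bundle$expression
        coll <- readGmt(bundle$files$gmt)
    }

    stageLog("building seeded networks")
    iomdn <- buildNeighborNetwork(
        ppi, GeneSet(c(immune@symbols, disease@symbols), name = "seeds"),
        name = "IOMDN")
    mgnd <- buildNeighborNetwork(iomdn, disease, name = "MGND")
    cmapI <- classifyNodes(iomdn, immune, disease)
    cmapM <- classifyNodes(mgnd, immune, disease)
    retention <- edgeRetention(mgnd, iomdn)
    stageLog("IOMDN: ", nodeCount(iomdn), " nodes / ", edgeCount(iomdn),
             " edges; MGND: ", nodeCount(mgnd), " nodes / ",
             edgeCount(mgnd), " edges; retention ", retention$percent)

    stageLog("topology")
    topoI <- topologySummary(iomdn)
    topoM <- topologySummary(mgnd)
    ddI <- degreeDistribution(iomdn)
    ddM <- degreeDistribution(mgnd)
    hubs <- hubAnalysis(iomdn, cmapI, k = 5L)

    stageLog("module detection (MCODE)")
    ms <- detectModules(mgnd)
    top <- rankModules(ms, th$topModules)
    stageLog("found ", length(ms), " modules; keeping top ", length(top))

    writeNetwork(iomdn, file.path(outDir, "iomdn.tsv"), "tsv-edge-list")
    writeNetwork(mgnd, file.path(outDir, "mgnd.tsv"), "tsv-edge-list")
    writeNetwork(mgnd, file.path(outDir, "mgnd.graphml"), "graphml",
                 categories = cmapM)
    writeCategoryMap(cmapI, file.path(outDir, "iomdn_categories.tsv"))
    writeCategoryMap(cmapM, file.path(outDir, "mgnd_categories.tsv"))
    moduleTable <- do.call(rbind, lapply(modules(top), function(m)
        data.frame(rank = m@rank, size = length(m@members),
                   score = m@score,
                   members = paste(m@members, collapse = ","))))
    if (!is.null(moduleTable))
        utils::write.table(moduleTable,
                           file.path(outDir, "top_modules.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)

    report <- list(
        metadata = list(package = "MGNet",
                        version = as.character(
                            utils::packageVersion("MGNet")),
                        seed = cfg$seed, thresholds = th,
                        synthetic = is.null(cfg$inputs)),
        networks = list(
            iomdn = list(nodes = nodeCount(iomdn),
                         edges = edgeCount(iomdn),
                         seedsUsed = length(seedsUsed(iomdn)),
                         tally = as.list(tallyCategories(cmapI)),
                         density = topoI$density,
                         meanDegree = topoI$meanDegree,
                         meanClustering = topoI$meanClustering,
                         loglogSlope = ddI$loglogSlope,
                         loglogR2 = ddI$loglogR2),
            mgnd = list(nodes = nodeCount(mgnd),
                        edges = edgeCount(mgnd),
                        seedsUsed = length(seedsUsed(mgnd)),
                        tally = as.list(tallyCategories(cmapM)),
                        density = topoM$density,
                        meanDegree = topoM$meanDegree,
                        meanClustering = topoM$meanClustering,
                        loglogSlope = ddM$loglogSlope,
                        loglogR2 = ddM$loglogR2)),
        retention = retention[c("subEdges", "baseEdges", "fraction",
                                "percent")],
        hubs = list(meanDegreeByCategory = as.list(hubs$meanDegree),
                    topHubs = hubs$topHubs),
        modules = list(total = length(ms),
                       top = lapply(modules(top), function(m)
                           list(rank = m@rank, size = length(m@members),
                                score = m@score, members = m@members))))

    if (!is.null(expr)) {
        stageLog("expression overlay")
        cors <- correlateEdges(mgnd, expr, group = "disease",
                               alpha = th$coexprAlpha,
                               strongThreshold = th$strongThreshold)
        corSummary <- classifyCorrelations(cors, alpha = th$coexprAlpha,
                                           strongThreshold =
                                               th$strongThreshold)
        dex <- differentialExpression(expr, variant = th$deVariant,
                                      alpha = th$deAlpha)
        utils::write.table(cors, file.path(outDir,
                                           "edge_correlations.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(dex, file.path(outDir,
                                          "differential_expression.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        moduleReports <- lapply(modules(top), function(m) {
            r <- moduleExpressionReport(m, dex, cors, id = m@rank)
            r$edgeCorrelations <- NULL
            r$positiveSignificant <- sum(
                cors$significant & cors$r > 0 &
                cors$from %in% m@members & cors$to %in% m@members,
                na.rm = TRUE)
            r$negativeSignificant <- sum(
                cors$significant & cors$r < 0 &
                cors$from %in% m@members & cors$to %in% m@members,
                na.rm = TRUE)
            r
        })
        report$coexpression <- corSummary[setdiff(names(corSummary),
                                                  character(0))]
        report$differentialExpression <- list(
            genesTested = nrow(dex),
            differential = sum(dex$differential),
            up = sum(dex$differential & dex$direction == "up"),
            down = sum(dex$differential & dex$direction == "down"))
        report$moduleExpression <- moduleReports
    }

    if (!is.null(coll) && length(top) > 0L) {
        stageLog("enrichment")
        query <- GeneSet(unlist(lapply(modules(top), members)),
                         name = "top_module_genes")
        background <- GeneSet(nodes(mgnd), name = "mgnd_nodes")
        enr <- overrepresent(query, coll, background,
                             alpha = th$enrichAlpha)
        dg <- drugGeneNetwork(enr, query)
        utils::write.table(enr, file.path(outDir, "enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(dg, file.path(outDir, "drug_gene_network.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        report$enrichment <- list(
            collection = coll@name, termsTested = nrow(enr),
            enriched = sum(enr$enriched),
            enrichedTerms = enr$term[enr$enriched],
            drugGeneEdges = nrow(dg))
    }

    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stageLog("report written to ", file.path(outDir, "report.json"))
    invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
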