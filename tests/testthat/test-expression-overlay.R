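tinyExpr <- function(values, genes, samples, group) {
    m <- matrix(values, nrow = length(genes), byrow = TRUE,
                dimnames = list(genes, samples))
    ExpressionData(m, structure(group, names = samples))
}

test_that("plain TSV expression loads with labels", {
    f <- withr::local_tempfile(lines = c(
        "gene\ts1\ts2\ts3\ts4",
        "A\t1\t2\t3\t4", "B\t2\t2\t2\t2", "C\t0.5\t1.5\t2.5\t3.5"))
    lab <- c(s1 = "disease", s2 = "disease", s3 = "control",
             s4 = "control")
    mat <- readExpression(f, "plain-tsv", lab)
    expect_equal(dim(exprValues(mat)), c(3L, 4L))
    expect_equal(unname(sampleGroups(mat)),
                 c("disease", "disease", "control", "control"))
    expect_error(readExpression(f, "plain-tsv", lab[1:3]), "unlabeled")
})

test_that("series-matrix dialect parses only the table block", {
    f <- withr::local_tempfile(lines = c(
        "!Series_title\t\"synthetic fixture\"",
        "!Sample_geo_accession\t\"GSM1\"\t\"GSM2\"\t\"GSM3\"\t\"GSM4\"",
        "!series_matrix_table_begin",
        "\"ID_REF\"\t\"GSM1\"\t\"GSM2\"\t\"GSM3\"\t\"GSM4\"",
        "\"A\"\t1\t2\t3\t4",
        "\"B\"\tNA\t5\t6\t7",
        "!series_matrix_table_end"))
    lab <- c(GSM1 = "disease", GSM2 = "disease", GSM3 = "control",
             GSM4 = "control")
    mat <- readExpression(f, "series-matrix", lab)
    v <- exprValues(mat)
    expect_equal(dim(v), c(2L, 4L))
    expect_true(is.na(v["B", "GSM1"]))
    expect_equal(v["A", ], c(GSM1 = 1, GSM2 = 2, GSM3 = 3, GSM4 = 4))
})

test_that("non-numeric cells are reported with coordinates", {
    f <- withr::local_tempfile(lines = c("gene\ts1\ts2",
                                         "A\t1\t2", "B\t3\toops"))
    expect_error(readExpression(f, "plain-tsv",
                                c(s1 = "disease", s2 = "control")),
                 "'oops'.*gene B.*sample s2")
})

test_that("missing cells use pairwise-complete observations", {
    samples <- paste0("s", 1:6)
    mat <- tinyExpr(c(1, 2, NA, 4, 5, 6,
                      2, 4, 9, 8, 10, 12), c("A", "B"), samples,
                    rep("disease", 6))
    net <- InteractionNetwork("A", "B")
    rec <- correlateEdges(net, mat, "disease")
    x <- c(1, 2, 4, 5, 6); y <- c(2, 4, 8, 10, 12)
    expect_equal(rec$n, 5L)
    expect_equal(rec$r, bfPearson(x, y), tolerance = 1e-12)
})

test_that("probe collapse follows both strategies and a group-by oracle", {
    samples <- paste0("s", 1:4)
    mat <- tinyExpr(c(5, 5, 5, 5,
                      7, 7, 7, 7,
                      1, 2, 3, 4), c("P1", "P2", "P3"), samples,
                    c("disease", "disease", "control", "control"))
    map <- c(P1 = "G", P2 = "G", P3 = "H")
    best <- collapseProbes(mat, map, "max-mean-probe")
    expect_equal(unname(exprValues(best)["G", ]), rep(7, 4))
    avg <- collapseProbes(mat, map, "mean")
    expect_equal(unname(exprValues(avg)["G", ]), rep(6, 4))
    ## random fixture vs brute-force group-by
    set.seed(99)
    v <- matrix(rnorm(40), nrow = 10,
                dimnames = list(sprintf("P%02d", 1:10), samples))
    m2 <- ExpressionData(v, structure(rep(c("disease", "control"), 2),
                                      names = samples))
    map2 <- structure(sample(c("G1", "G2", "G3", "G4"), 10, replace = TRUE),
                      names = rownames(v))
    got <- exprValues(collapseProbes(m2, map2, "mean"))
    for (g in unique(map2)) {
        rows <- names(map2)[map2 == g]
        expect_equal(unname(got[g, ]),
                     unname(colMeans(v[rows, , drop = FALSE])))
    }
})

test_that("edge correlation p-values reproduce the worked examples", {
    ## r = -0.7 and r = -0.48 at n = 21 disease samples, via the t
    ## transform on 19 df; the published table prints 0.00042 and 0.027
    ## from an unrounded r, so agreement is asserted at the precision the
    ## rounding of r to 2 decimals supports
    p1 <- MGNet:::pearsonPValue(-0.7, 21)
    p2 <- MGNet:::pearsonPValue(-0.48, 21)
    expect_equal(p1, 0.00042, tolerance = 0.05)
    expect_equal(p2, 0.027, tolerance = 0.05)
    ## symmetry and monotonicity of the transform
    expect_equal(MGNet:::pearsonPValue(0.7, 21), p1)
    rs <- seq(0.05, 0.95, by = 0.05)
    ps <- vapply(rs, MGNet:::pearsonPValue, numeric(1), n = 21)
    expect_true(all(diff(ps) < 0))
})

test_that("correlations match the naive sum formula on random vectors", {
    set.seed(111)
    samples <- paste0("s", 1:12)
    for (rep in 1:5) {
        v <- matrix(rnorm(24), nrow = 2,
                    dimnames = list(c("A", "B"), samples))
        mat <- ExpressionData(v, structure(rep("disease", 12),
                                           names = samples))
        rec <- correlateEdges(InteractionNetwork("A", "B"), mat, "disease")
        expect_equal(rec$r, bfPearson(v[1, ], v[2, ]), tolerance = 1e-10)
    }
})

test_that("degenerate and invalid edges are flagged, not summarized", {
    samples <- paste0("s", 1:5)
    mat <- tinyExpr(c(1, 2, 3, 4, 5,
                      1, 2, 3, 4, 5,
                      2, 2, 2, 2, 2), c("A", "B", "C"), samples,
                    rep("disease", 5))
    net <- InteractionNetwork(c("A", "A", "A"), c("B", "C", "D"))
    rec <- correlateEdges(net, mat, "disease")
    ab <- rec[rec$to == "B", ]
    expect_true(ab$degenerate)
    expect_equal(ab$r, 1)
    expect_true(ab$p > 0)
    expect_false(rec[rec$to == "C", "valid"])    # zero variance
    expect_false(rec[rec$to == "D", "computed"]) # gene absent
    cs <- classifyCorrelations(rec)
    expect_equal(cs$validEdges, 1L)
})

test_that("correlation summaries apply the significance and strong rules", {
    rec <- data.frame(from = c("A", "B", "C"), to = c("B", "C", "D"),
                      r = c(0.6, -0.3, 0.9), n = 21,
                      p = c(0.01, 0.04, 0.2), q = NA,
                      significant = NA, strong = NA,
                      computed = TRUE, valid = TRUE, degenerate = FALSE)
    cs <- classifyCorrelations(rec)
    expect_equal(cs$significantCount, 2L)
    expect_equal(cs$strongAmongSignificant, 1L)
    expect_equal(cs$strongShare, 0.5)
    expect_equal(cs$positiveCount, 1L)
    expect_equal(cs$negativeCount, 1L)
    empty <- classifyCorrelations(rec[0, ])
    expect_equal(empty$significantCount, 0L)
    expect_equal(empty$significantPercent, "0.00%")
})

test_that("differential expression matches a hand-computed t-test", {
    samples <- paste0("s", 1:6)
    mat <- tinyExpr(c(5, 6, 7, 1, 2, 3), "G", samples,
                    rep(c("disease", "control"), each = 3))
    dex <- differentialExpression(mat, "student")
    ## pooled-variance t by hand: means 6 vs 2, sp^2 = 1, se = sqrt(2/3)
    tHand <- (6 - 2) / sqrt(1 * (1 / 3 + 1 / 3))
    expect_equal(dex$t, tHand, tolerance = 1e-12)
    expect_equal(dex$p, 2 * pt(-tHand, 4), tolerance = 1e-12)
    expect_equal(dex$direction, "up")
    ## identical groups: p ~ 1, not differential
    flat <- tinyExpr(c(1, 2, 3, 1, 2, 3), "G", samples,
                     rep(c("disease", "control"), each = 3))
    dft <- differentialExpression(flat)
    expect_gt(dft$p, 0.99)
    expect_false(dft$differential)
})

test_that("swapping group labels flips t and direction but not p", {
    set.seed(123)
    samples <- paste0("s", 1:10)
    v <- matrix(rnorm(30, mean = rep(c(0, 1, 2), each = 10)), nrow = 3,
                byrow = FALSE, dimnames = list(c("A", "B", "C"), samples))
    g1 <- rep(c("disease", "control"), each = 5)
    g2 <- rep(c("control", "disease"), each = 5)
    d1 <- differentialExpression(ExpressionData(v, structure(g1,
                                                             names = samples)))
    d2 <- differentialExpression(ExpressionData(v, structure(g2,
                                                             names = samples)))
    expect_equal(d1$t, -d2$t, tolerance = 1e-12)
    expect_equal(d1$p, d2$p, tolerance = 1e-12)
    expect_true(all(d1$direction != d2$direction |
                    d1$meanDisease == d1$meanControl))
})

test_that("genes with too few observations per group are skipped", {
    samples <- paste0("s", 1:8)
    v <- matrix(rnorm(16), nrow = 2,
                dimnames = list(c("A", "B"), samples))
    v[1, 1:3] <- NA  # gene A: only 1 disease observation left
    mat <- ExpressionData(v, structure(rep(c("disease", "control"),
                                           each = 4), names = samples))
    expect_warning(dex <- differentialExpression(mat), "skipped")
    expect_equal(dex$gene, "B")
})

test_that("module expression reports tally flags over members only", {
    dex <- data.frame(gene = c("A", "B", "C", "D", "E"),
                      meanDisease = 1, meanControl = 0, t = 1,
                      p = c(0.01, 0.01, 0.5, 0.02, 0.001), q = NA,
                      direction = c("up", "down", "up", "up", "down"),
                      differential = c(TRUE, TRUE, FALSE, TRUE, TRUE))
    cors <- data.frame(from = c("A", "A", "D"), to = c("B", "E", "E"),
                       r = c(0.9, 0.2, -0.6), n = 21,
                       p = c(0.001, 0.5, 0.01), q = NA,
                       significant = c(TRUE, FALSE, TRUE),
                       strong = c(TRUE, FALSE, TRUE),
                       computed = TRUE, valid = TRUE, degenerate = FALSE)
    rep1 <- moduleExpressionReport(c("A", "B", "C", "D"), dex, cors, id = 1)
    expect_equal(rep1$geneCount, 4L)
    expect_equal(rep1$differentialCount, 3L)
    expect_equal(rep1$upCount, 2L)
    expect_equal(rep1$downCount, 1L)
    expect_equal(nrow(rep1$edgeCorrelations), 1L)  # only A-B is internal
    ## no internal edges: empty table, counts intact
    rep2 <- moduleExpressionReport(c("C", "D"), dex, cors)
    expect_equal(nrow(rep2$edgeCorrelations), 0L)
    expect_equal(rep2$differentialCount, 1L)
})
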