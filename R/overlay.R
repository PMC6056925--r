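## Expression overlay on a network: edge-wise Pearson co-expression with
## two-sided significance, correlation summaries, unpaired differential
## expression, and per-module reports.

## two-sided p for a Pearson r at n complete pairs via the t transform
## t = r sqrt((n-2)/(1-r^2)) on n-2 df (exact under bivariate normality)
pearsonPValue <- function(r, n) {
    df <- n - 2
    if (df < 1) return(NA_real_)
    if (abs(r) >= 1) return(.Machine$double.xmin)
    t <- r * sqrt(df / (1 - r^2))
    max(2 * stats::pt(-abs(t), df), .Machine$double.xmin)
}

#' Edge-wise Pearson correlations on a network
#'
#' For every network edge whose two genes are both present in the
#' expression matrix, computes the Pearson correlation over the chosen
#' sample group using pairwise-complete observations, with a two-sided
#' p-value from the t transform and a Benjamini-Hochberg q-value across
#' all valid edges.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param mat an \linkS4class{ExpressionData} with unique gene rownames.
#' @param group \code{"disease"} (default, matching a disease-samples-only
#'   co-expression analysis), \code{"control"}, or \code{"all"}.
#' @param alpha two-sided significance level for the \code{significant}
#'   flag (default 0.05).
#' @param strongThreshold absolute-correlation threshold for the
#'   \code{strong} flag (default 0.5).
#' @return data frame with one row per edge: \code{from}, \code{to},
#'   \code{r}, \code{n}, \code{p}, \code{q}, \code{significant},
#'   \code{strong}, \code{computed} (both genes measured), \code{valid}
#'   (enough complete pairs and non-zero variance), \code{degenerate}
#'   (|r| = 1, p reported at the representable minimum).
#' @export
correlateEdges <- function(net, mat, group = c("disease", "control", "all"),
                           alpha = 0.05, strongThreshold = 0.5) {
    group <- match.arg(group)
    v <- exprValues(mat)
    if (anyDuplicated(rownames(v)))
        stop("expression matrix has duplicate gene symbols; ",
             "collapse probes first (see collapseProbes)")
    g <- sampleGroups(mat)
    cols <- if (group == "all") seq_along(g) else which(g == group)
    if (length(cols) < 4L)
        stop("need at least 4 samples in group '", group, "'")
    v <- v[, cols, drop = FALSE]
    e <- net@edges
    nE <- nrow(e)
    r <- rep(NA_real_, nE); n <- integer(nE); p <- rep(NA_real_, nE)
    computed <- e[, 1L] %in% rownames(v) & e[, 2L] %in% rownames(v)
    degenerate <- logical(nE)
    for (i in which(computed)) {
        x <- v[e[i, 1L], ]; y <- v[e[i, 2L], ]
        ok <- !is.na(x) & !is.na(y)
        n[i] <- sum(ok)
        if (n[i] < 4L) next
        x <- x[ok]; y <- y[ok]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) next
        r[i] <- stats::cor(x, y)
        if (abs(r[i]) >= 1 - 1e-12) degenerate[i] <- TRUE
        p[i] <- pearsonPValue(r[i], n[i])
    }
    valid <- computed & !is.na(r)
    q <- rep(NA_real_, nE)
    q[valid] <- stats::p.adjust(p[valid], method = "BH")
    data.frame(from = e[, 1L], to = e[, 2L], r = r, n = n, p = p, q = q,
               significant = !is.na(p) & p < alpha,
               strong = !is.na(r) & abs(r) > strongThreshold,
               computed = computed, valid = valid, degenerate = degenerate,
               stringsAsFactors = FALSE)
}

#' Summarize edge correlations
#'
#' Applies the significance and strong-correlation rules to an edge
#' correlation table and tallies the headline quantities: share of
#' significantly co-expressed interactions among valid edges, share of
#' strong correlations among the significant ones, and the positive /
#' negative split of significant correlations.
#'
#' @param records data frame from \code{\link{correlateEdges}}.
#' @param alpha significance level (p < alpha), default 0.05.
#' @param strongThreshold strong-correlation cutoff (|r| > threshold),
#'   default 0.5.
#' @return list of counts and shares; shares are also rendered to
#'   2-decimal percent strings.
#' @export
classifyCorrelations <- function(records, alpha = 0.05,
                                 strongThreshold = 0.5) {
    if (nrow(records) == 0L)
        return(list(totalEdges = 0L, computedEdges = 0L, validEdges = 0L,
                    significantCount = 0L, significantShare = 0,
                    strongAmongSignificant = 0L, strongShare = 0,
                    positiveCount = 0L, negativeCount = 0L,
                    significantPercent = "0.00%", strongPercent = "0.00%"))
    valid <- records$valid
    sig <- valid & !is.na(records$p) & records$p < alpha
    strong <- sig & abs(records$r) > strongThreshold
    nValid <- sum(valid); nSig <- sum(sig); nStrong <- sum(strong)
    sigShare <- if (nValid) nSig / nValid else 0
    strongShare <- if (nSig) nStrong / nSig else 0
    list(totalEdges = nrow(records), computedEdges = sum(records$computed),
         validEdges = nValid, significantCount = nSig,
         significantShare = sigShare,
         strongAmongSignificant = nStrong, strongShare = strongShare,
         positiveCount = sum(sig & records$r > 0),
         negativeCount = sum(sig & records$r < 0),
         significantPercent = sprintf("%.2f%%", 100 * sigShare),
         strongPercent = sprintf("%.2f%%", 100 * strongShare))
}

#' Differential expression between disease and control samples
#'
#' Per-gene two-sided unpaired t-test (Welch by default; Student's
#' equal-variance variant available), direction signed by the
#' disease-minus-control mean difference, with Benjamini-Hochberg q-values
#' reported alongside the raw p-values. Genes with fewer than 3 non-missing
#' observations in either group are skipped with a warning.
#'
#' @param mat an \linkS4class{ExpressionData}.
#' @param variant \code{"welch"} (default) or \code{"student"}.
#' @param alpha significance level for the \code{differential} flag
#'   (raw p < alpha; default 0.05).
#' @return data frame: \code{gene}, \code{meanDisease}, \code{meanControl},
#'   \code{t}, \code{p}, \code{q}, \code{direction} ("up"/"down"),
#'   \code{differential}.
#' @export
differentialExpression <- function(mat, variant = c("welch", "student"),
                                   alpha = 0.05) {
    variant <- match.arg(variant)
    v <- exprValues(mat)
    g <- sampleGroups(mat)
    dCols <- which(g == "disease"); cCols <- which(g == "control")
    if (length(dCols) < 3L || length(cCols) < 3L)
        stop("need at least 3 samples per group")
    genes <- rownames(v)
    res <- vector("list", length(genes))
    skipped <- 0L
    for (i in seq_along(genes)) {
        x <- v[i, dCols]; x <- x[!is.na(x)]
        y <- v[i, cCols]; y <- y[!is.na(y)]
        if (length(x) < 3L || length(y) < 3L) {
            skipped <- skipped + 1L
            next
        }
        tt <- tryCatch(
            stats::t.test(x, y, var.equal = (variant == "student")),
            error = function(e) NULL)
        md <- mean(x); mc <- mean(y)
        res[[i]] <- data.frame(
            gene = genes[i], meanDisease = md, meanControl = mc,
            t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
            p = if (is.null(tt)) NA_real_ else tt$p.value,
            direction = if (md >= mc) "up" else "down",
            stringsAsFactors = FALSE)
    }
    if (skipped)
        warning(skipped, " gene(s) skipped: fewer than 3 observations ",
                "in a group")
    out <- do.call(rbind, res)
    if (is.null(out))
        return(data.frame(gene = character(0), meanDisease = numeric(0),
                          meanControl = numeric(0), t = numeric(0),
                          p = numeric(0), q = numeric(0),
                          direction = character(0),
                          differential = logical(0)))
    out$q <- stats::p.adjust(out$p, method = "BH")
    out$differential <- !is.na(out$p) & out$p < alpha
    rownames(out) <- NULL
    out[, c("gene", "meanDisease", "meanControl", "t", "p", "q",
            "direction", "differential")]
}

#' Expression report for one module
#'
#' Restricts differential-expression calls and edge correlations to a
#' module's members and tallies total / differential / up / down counts.
#'
#' @param module a \linkS4class{Module} (or character vector of members).
#' @param dex data frame from \code{\link{differentialExpression}}.
#' @param cors data frame from \code{\link{correlateEdges}}.
#' @param id module identifier for the report.
#' @return list with \code{id}, \code{geneCount}, \code{differentialCount},
#'   \code{upCount}, \code{downCount}, and \code{edgeCorrelations} (the
#'   correlation rows whose both endpoints are members).
#' @export
moduleExpressionReport <- function(module, dex, cors, id = NA) {
    mem <- if (is(module, "Module")) module@members else toupper(module)
    d <- dex[dex$gene %in% mem, , drop = FALSE]
    diffD <- d[d$differential, , drop = FALSE]
    ec <- cors[cors$from %in% mem & cors$to %in% mem, , drop = FALSE]
    list(id = id, geneCount = length(mem),
         differentialCount = nrow(diffD),
         upCount = sum(diffD$direction == "up"),
         downCount = sum(diffD$direction == "down"),
         edgeCorrelations = ec)
}
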