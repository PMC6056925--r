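## Local over-representation analysis against GMT gene-set collections
## (GO / KEGG / drug-target sets), plus the drug-gene bipartite network.

#' Read a GMT gene-set collection
#'
#' Standard GMT layout: term, description, then member genes, all
#' tab-separated. Symbols are uppercased and deduplicated; empty sets are
#' dropped with a warning.
#'
#' @param path GMT file path.
#' @param name collection label.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGmt <- function(path, name = basename(path)) {
    if (!file.exists(path)) stop("cannot read GMT file: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    sets <- list()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 2L)
            stop("malformed GMT line ", i, ": fewer than 2 columns")
        genes <- unique(toupper(trimws(f[-(1:2)])))
        genes <- genes[nzchar(genes)]
        if (!length(genes)) {
            warning("GMT term '", f[1L], "' has no genes; dropped")
            next
        }
        if (f[1L] %in% names(sets))
            stop("duplicate GMT term name '", f[1L], "' at line ", i)
        sets[[f[1L]]] <- genes
    }
    new("GeneSetCollection", name = name, sets = sets,
        universe = character(0))
}

#' Write a GMT gene-set collection
#'
#' @param coll a \linkS4class{GeneSetCollection} or named list of character
#'   vectors.
#' @param path destination file.
#' @export
writeGmt <- function(coll, path) {
    sets <- if (is(coll, "GeneSetCollection")) coll@sets else coll
    lines <- vapply(names(sets), function(term)
        paste(c(term, term, sets[[term]]), collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each term, tests whether the query set overlaps the term's gene set
#' more than expected when drawing \code{n} genes from the background of
#' size \code{N}: p = P(X >= k) with X hypergeometric(K, N - K, n). Query
#' genes outside the background are dropped with a warning; term sets are
#' intersected with the background. Benjamini-Hochberg q-values are
#' computed across all tested terms.
#'
#' @param query a \linkS4class{GeneSet} or character vector.
#' @param coll a \linkS4class{GeneSetCollection}.
#' @param background a \linkS4class{GeneSet} or character vector (e.g. all
#'   genes of the analyzed network).
#' @param alpha enrichment cutoff on the raw p-value (default 0.01).
#' @return data frame sorted by ascending p: \code{term}, \code{k}
#'   (overlap), \code{K} (term size in background), \code{n} (query size),
#'   \code{N} (background size), \code{p}, \code{q}, \code{enriched},
#'   \code{overlapGenes} (comma-separated).
#' @export
overrepresent <- function(query, coll, background, alpha = 0.01) {
    q <- if (is(query, "GeneSet")) query@symbols else
        unique(toupper(query))
    bg <- if (is(background, "GeneSet")) background@symbols else
        unique(toupper(background))
    outside <- setdiff(q, bg)
    if (length(outside)) {
        warning(length(outside),
                " query gene(s) outside the background dropped")
        q <- intersect(q, bg)
    }
    if (!length(q)) {
        warning("empty query after background filtering")
        return(data.frame(term = character(0), k = integer(0),
                          K = integer(0), n = integer(0), N = integer(0),
                          p = numeric(0), q = numeric(0),
                          enriched = logical(0),
                          overlapGenes = character(0)))
    }
    N <- length(bg); n <- length(q)
    terms <- names(coll@sets)
    k <- integer(length(terms)); K <- integer(length(terms))
    pv <- numeric(length(terms)); ov <- character(length(terms))
    for (i in seq_along(terms)) {
        termSet <- intersect(coll@sets[[i]], bg)
        K[i] <- length(termSet)
        hit <- intersect(q, termSet)
        k[i] <- length(hit)
        ov[i] <- paste(sort(hit), collapse = ",")
        pv[i] <- stats::phyper(k[i] - 1L, K[i], N - K[i], n,
                               lower.tail = FALSE)
    }
    res <- data.frame(term = terms, k = k, K = K, n = n, N = N, p = pv,
                      q = stats::p.adjust(pv, method = "BH"),
                      enriched = pv < alpha, overlapGenes = ov,
                      stringsAsFactors = FALSE)
    res <- res[order(res$p, res$term), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Bipartite term-gene network from enrichment results
#'
#' One edge per (enriched term, overlap gene) pair — e.g. the drug-target
#' network over module genes.
#'
#' @param results data frame from \code{\link{overrepresent}}.
#' @param query the query \linkS4class{GeneSet} or character vector
#'   (edges are restricted to query genes).
#' @return data frame with columns \code{term} and \code{gene}.
#' @export
drugGeneNetwork <- function(results, query) {
    q <- if (is(query, "GeneSet")) query@symbols else unique(toupper(query))
    enr <- results[results$enriched, , drop = FALSE]
    if (!nrow(enr))
        return(data.frame(term = character(0), gene = character(0)))
    pieces <- lapply(seq_len(nrow(enr)), function(i) {
        genes <- strsplit(enr$overlapGenes[i], ",", fixed = TRUE)[[1L]]
        genes <- intersect(genes, q)
        if (!length(genes)) return(NULL)
        data.frame(term = enr$term[i], gene = genes,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, pieces)
    if (is.null(out)) data.frame(term = character(0), gene = character(0))
    else { rownames(out) <- NULL; out }
}
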