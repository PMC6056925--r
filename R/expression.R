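## Expression input: GEO series-matrix / plain TSV readers and probe
## collapsing.

#' Read an expression matrix with sample group labels
#'
#' Dialects: \code{"plain-tsv"} (header row of sample IDs, first column
#' gene/probe symbols) and \code{"series-matrix"} (GEO series-matrix text
#' export; only the block between \code{!series_matrix_table_begin} and
#' \code{!series_matrix_table_end} is parsed). Empty cells, \code{NA} and
#' \code{null} become missing values; any other non-numeric cell is a parse
#' error reporting its row and column.
#'
#' @param path file path.
#' @param dialect \code{"plain-tsv"} or \code{"series-matrix"}.
#' @param labels sample group labels: a named character vector
#'   (sample -> "disease"/"control"), or a data frame / path to a TSV with
#'   columns \code{sample} and \code{group}.
#' @return an \linkS4class{ExpressionData}.
#' @export
readExpression <- function(path, dialect = c("plain-tsv", "series-matrix"),
                           labels) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("cannot read expression file: ", path)
    lines <- readLines(path, warn = FALSE)
    if (dialect == "series-matrix") {
        b <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
        e <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
        if (length(b) != 1L || length(e) != 1L || e <= b + 1L)
            stop("series-matrix table markers not found in ", path)
        lines <- lines[(b + 1L):(e - 1L)]
    }
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    header <- gsub("\"", "", fields[[1L]], fixed = TRUE)
    sampleIds <- header[-1L]
    body <- fields[-1L]
    badLen <- which(lengths(body) != length(header))
    if (length(badLen))
        stop("expression table row ", badLen[1L] + 1L,
             " has ", lengths(body)[badLen[1L]], " fields; expected ",
             length(header))
    genes <- toupper(gsub("\"", "", vapply(body, `[[`, character(1), 1L),
                          fixed = TRUE))
    vals <- matrix(NA_real_, nrow = length(body), ncol = length(sampleIds),
                   dimnames = list(genes, sampleIds))
    for (i in seq_along(body)) {
        cells <- body[[i]][-1L]
        cells[cells %in% c("", "NA", "na", "null", "NULL")] <- NA
        num <- suppressWarnings(as.numeric(cells))
        bad <- which(!is.na(cells) & is.na(num))
        if (length(bad))
            stop("non-numeric expression value '", cells[bad[1L]],
                 "' at row ", i + 1L, " (gene ", genes[i], "), column ",
                 bad[1L] + 1L, " (sample ", sampleIds[bad[1L]], ")")
        vals[i, ] <- num
    }
    if (is.character(labels) && length(labels) == 1L && file.exists(labels))
        labels <- utils::read.delim(labels, stringsAsFactors = FALSE)
    if (is.data.frame(labels)) {
        if (!all(c("sample", "group") %in% colnames(labels)))
            stop("label table must have 'sample' and 'group' columns")
        labels <- structure(labels$group, names = labels$sample)
    }
    unlabeled <- setdiff(sampleIds, names(labels))
    if (length(unlabeled))
        stop("unlabeled sample(s): ", paste(unlabeled, collapse = ", "))
    ExpressionData(vals, labels[sampleIds])
}

#' Collapse probes to genes
#'
#' @param mat an \linkS4class{ExpressionData} whose rownames are probe IDs.
#' @param probe2gene named character vector mapping probe -> gene symbol.
#'   Probes without a mapping are kept under their own ID (a message reports
#'   how many).
#' @param strategy \code{"max-mean-probe"} keeps, per gene, the probe with
#'   the highest mean expression (missing values removed); \code{"mean"}
#'   averages the probes elementwise.
#' @return an \linkS4class{ExpressionData} with one row per gene.
#' @export
collapseProbes <- function(mat, probe2gene,
                           strategy = c("max-mean-probe", "mean")) {
    strategy <- match.arg(strategy)
    v <- exprValues(mat)
    probes <- rownames(v)
    gene <- toupper(unname(probe2gene[probes]))
    unmapped <- is.na(gene)
    if (any(unmapped)) {
        message("collapseProbes: ", sum(unmapped),
                " probe(s) without a gene mapping kept under their probe ID")
        gene[unmapped] <- probes[unmapped]
    }
    rowsByGene <- split(seq_along(probes), gene)
    out <- matrix(NA_real_, nrow = length(rowsByGene), ncol = ncol(v),
                  dimnames = list(names(rowsByGene), colnames(v)))
    for (i in seq_along(rowsByGene)) {
        rows <- rowsByGene[[i]]
        if (length(rows) == 1L) {
            out[i, ] <- v[rows, ]
        } else if (strategy == "max-mean-probe") {
            means <- rowMeans(v[rows, , drop = FALSE], na.rm = TRUE)
            out[i, ] <- v[rows[which.max(means)], ]
        } else {
            out[i, ] <- colMeans(v[rows, , drop = FALSE], na.rm = TRUE)
        }
    }
    out[is.nan(out)] <- NA_real_
    ExpressionData(out, sampleGroups(mat))
}
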