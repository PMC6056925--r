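## Seed gene catalogs: readers, node classification, category tallies.

#' Read a seed gene set from a file
#'
#' Three dialects are supported: \code{"plain-list"} (one symbol per line,
#' \code{#} comments), \code{"gaf"} (GAF 2.x annotation files: tab-separated,
#' \code{!} comment lines, object symbol in column 3), and
#' \code{"two-column-tsv"} (tab-separated, gene symbol taken from
#' \code{geneColumn}, header detected via \code{header}).
#'
#' @param path file path.
#' @param dialect one of \code{"plain-list"}, \code{"gaf"},
#'   \code{"two-column-tsv"}.
#' @param name label for the resulting set.
#' @param geneColumn for \code{two-column-tsv}: column index or name holding
#'   the gene symbol (default 2).
#' @param header for \code{two-column-tsv}: does the file have a header row?
#' @return a \linkS4class{GeneSet}; provenance records path and dialect.
#' @export
readGeneSet <- function(path,
                        dialect = c("plain-list", "gaf", "two-column-tsv"),
                        name = basename(path), geneColumn = 2L,
                        header = FALSE) {
    dialect <- match.arg(dialect)
    if (!file.exists(path))
        stop("cannot read gene set file: ", path)
    raw <- switch(dialect,
        "plain-list" = {
            lines <- readLines(path, warn = FALSE)
            lines <- trimws(sub("#.*$", "", lines))
            lines[nzchar(lines)]
        },
        "gaf" = {
            lines <- readLines(path, warn = FALSE)
            lines <- lines[!startsWith(lines, "!") & nzchar(trimws(lines))]
            if (!length(lines)) character(0)
            else {
                fields <- strsplit(lines, "\t", fixed = TRUE)
                short <- which(lengths(fields) < 3L)
                if (length(short))
                    stop("GAF line ", short[1L], " has fewer than 3 columns")
                vapply(fields, `[[`, character(1), 3L)
            }
        },
        "two-column-tsv" = {
            tab <- utils::read.delim(path, header = header,
                                     stringsAsFactors = FALSE,
                                     comment.char = "#")
            if (is.character(geneColumn) &&
                !geneColumn %in% colnames(tab))
                stop("column '", geneColumn, "' not found in ", path)
            as.character(tab[[geneColumn]])
        })
    gs <- GeneSet(raw, name = name,
                  provenance = paste0(path, " [", dialect, "]"))
    if (length(gs@symbols) == 0L)
        stop("no gene symbols parsed from ", path, " (dialect ", dialect, ")")
    gs
}

#' Classify network nodes against immune and disease seed sets
#'
#' Each node falls in exactly one category: \code{BOTH} (in both seed sets),
#' \code{DISEASE_ONLY}, \code{IMMUNE_ONLY}, or \code{OTHER}.
#'
#' @param nodes character vector of node symbols (or an
#'   \linkS4class{InteractionNetwork}).
#' @param immune,disease \linkS4class{GeneSet}s (or character vectors).
#' @return a named factor (levels \code{BOTH}, \code{DISEASE_ONLY},
#'   \code{IMMUNE_ONLY}, \code{OTHER}) over the nodes.
#' @examples
#' classifyNodes(c("A", "B", "C", "D"), GeneSet(c("A", "B")),
#'               GeneSet(c("B", "C")))
#' @export
classifyNodes <- function(nodes, immune, disease) {
    if (is(nodes, "InteractionNetwork")) nodes <- nodes@nodes
    nodes <- toupper(as.character(nodes))
    imm <- if (is(immune, "GeneSet")) immune@symbols else toupper(immune)
    dis <- if (is(disease, "GeneSet")) disease@symbols else toupper(disease)
    inImm <- nodes %in% imm
    inDis <- nodes %in% dis
    cat <- ifelse(inImm & inDis, "BOTH",
           ifelse(inDis, "DISEASE_ONLY",
           ifelse(inImm, "IMMUNE_ONLY", "OTHER")))
    structure(factor(cat, levels = NODE_CATEGORIES), names = nodes)
}

#' Tally a category map
#'
#' @param cmap named factor as returned by \code{\link{classifyNodes}}.
#' @return named integer vector with one count per category plus
#'   \code{total}.
#' @examples
#' tallyCategories(classifyNodes(LETTERS[1:4], GeneSet("A"), GeneSet("B")))
#' @export
tallyCategories <- function(cmap) {
    cmap <- factor(cmap, levels = NODE_CATEGORIES)
    counts <- table(cmap)
    out <- c(as.integer(counts), length(cmap))
    names(out) <- c(NODE_CATEGORIES, "total")
    out
}

#' Write a category map as two-column TSV
#'
#' @param cmap named factor from \code{\link{classifyNodes}}.
#' @param path destination file.
#' @export
writeCategoryMap <- function(cmap, path) {
    utils::write.table(
        data.frame(node = names(cmap), category = as.character(cmap)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a category map written by \code{\link{writeCategoryMap}}
#'
#' @param path file path.
#' @return named factor over nodes.
#' @export
readCategoryMap <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    structure(factor(tab$category, levels = NODE_CATEGORIES),
              names = tab$node)
}
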