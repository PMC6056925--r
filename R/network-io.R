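## Readers and writers for PPI networks: TSV edge lists, SIF, GraphML,
## and the HPRD binary flat-file layout.

#' Read a protein-protein interaction network
#'
#' Dialects:
#' \describe{
#'   \item{tsv-edge-list}{tab-separated, endpoints in the first two fields;
#'     \code{#} comment lines skipped; a single-field line declares an
#'     isolated node.}
#'   \item{sif}{simple interaction format: \code{source relation target...};
#'     a line fans out to one edge per target; a single-field line is an
#'     isolated node. Tab-delimited if the line contains tabs, otherwise
#'     whitespace-delimited.}
#'   \item{hprd-binary-flat}{tab-separated flat file with gene symbols in
#'     columns 1 and 4 (HPRD binary-interaction layout); override with
#'     \code{symbolColumns}.}
#' }
#' Symbols are uppercased; self-loops and duplicate (or reversed-duplicate)
#' edges are dropped, with a message reporting how many.
#'
#' @param path file path.
#' @param dialect one of \code{"tsv-edge-list"}, \code{"sif"},
#'   \code{"hprd-binary-flat"}.
#' @param name network label (defaults to the file name).
#' @param symbolColumns integer pair: symbol columns for the HPRD layout.
#' @return an \linkS4class{InteractionNetwork}.
#' @export
readNetwork <- function(path,
                        dialect = c("tsv-edge-list", "sif",
                                    "hprd-binary-flat"),
                        name = basename(path), symbolColumns = c(1L, 4L)) {
    dialect <- match.arg(dialect)
    if (!file.exists(path))
        stop("cannot read network file: ", path)
    lines <- readLines(path, warn = FALSE)
    keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
    lineNo <- which(keep)
    lines <- lines[keep]
    from <- character(0); to <- character(0); isolated <- character(0)
    if (dialect == "tsv-edge-list") {
        fields <- strsplit(lines, "\t", fixed = TRUE)
        ## allow whitespace-separated fallback for single-field tab splits
        fields <- lapply(fields, function(f)
            if (length(f) == 1L) strsplit(trimws(f), "[[:space:]]+")[[1L]]
            else trimws(f))
        nf <- lengths(fields)
        one <- nf == 1L
        isolated <- vapply(fields[one], `[[`, character(1), 1L)
        f2 <- fields[!one]
        from <- vapply(f2, `[[`, character(1), 1L)
        to <- vapply(f2, `[[`, character(1), 2L)
    } else if (dialect == "sif") {
        for (i in seq_along(lines)) {
            ln <- lines[i]
            f <- if (grepl("\t", ln, fixed = TRUE))
                trimws(strsplit(ln, "\t", fixed = TRUE)[[1L]])
            else strsplit(trimws(ln), "[[:space:]]+")[[1L]]
            f <- f[nzchar(f)]
            if (length(f) == 1L) {
                isolated <- c(isolated, f)
            } else if (length(f) == 2L) {
                stop("malformed SIF line ", lineNo[i],
                     ": relation without target")
            } else {
                from <- c(from, rep(f[1L], length(f) - 2L))
                to <- c(to, f[-(1:2)])
            }
        }
    } else { # hprd-binary-flat
        fields <- strsplit(lines, "\t", fixed = TRUE)
        short <- which(lengths(fields) < max(symbolColumns))
        if (length(short))
            stop("malformed line ", lineNo[short[1L]], ": expected at least ",
                 max(symbolColumns), " tab-separated columns")
        from <- vapply(fields, `[[`, character(1), symbolColumns[1L])
        to <- vapply(fields, `[[`, character(1), symbolColumns[2L])
    }
    can <- canonicalizeEdges(from, to)
    if (can$nLoops + can$nDups > 0L)
        message("readNetwork: dropped ", can$nLoops, " self-loop(s) and ",
                can$nDups, " duplicate edge record(s) from ", path)
    net <- InteractionNetwork(from = from, to = to, nodes = isolated,
                              name = name)
    if (edgeCount(net) == 0L && dialect != "sif")
        stop("no edges parsed from ", path)
    net
}

#' Write a network to disk
#'
#' Formats: \code{tsv-edge-list} (one edge per line, isolated nodes as
#' single-field lines), \code{sif} (relation \code{pp}), and \code{graphml}
#' (via igraph; a category map, if given, is attached as the string node
#' attribute \code{"category"}). All three round-trip through
#' \code{\link{readNetwork}} with identical node and edge sets.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param path destination file.
#' @param format one of \code{"tsv-edge-list"}, \code{"sif"},
#'   \code{"graphml"}.
#' @param categories optional named factor from \code{\link{classifyNodes}}.
#' @return the path, invisibly.
#' @export
writeNetwork <- function(net, path,
                         format = c("tsv-edge-list", "sif", "graphml"),
                         categories = NULL) {
    format <- match.arg(format)
    e <- net@edges
    deg <- nodeDegrees(net)
    iso <- names(deg)[deg == 0L]
    if (format == "tsv-edge-list") {
        lines <- c(paste(e[, 1L], e[, 2L], sep = "\t"), iso)
        writeLines(lines, path)
    } else if (format == "sif") {
        lines <- c(paste(e[, 1L], "pp", e[, 2L], sep = "\t"), iso)
        writeLines(lines, path)
    } else {
        g <- asIgraph(net)
        if (!is.null(categories))
            igraph::V(g)$category <-
                as.character(categories[igraph::V(g)$name])
        igraph::write_graph(g, path, format = "graphml")
    }
    invisible(path)
}

#' Read a GraphML network (with optional category attribute)
#'
#' @param path GraphML file written by \code{\link{writeNetwork}} (or any
#'   undirected GraphML graph with named vertices).
#' @param name network label.
#' @return list with elements \code{network} and \code{categories} (named
#'   factor, or NULL when the file carries no category attribute).
#' @export
readGraphml <- function(path, name = basename(path)) {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_edgelist(g, names = TRUE)
    net <- InteractionNetwork(from = el[, 1L], to = el[, 2L],
                              nodes = igraph::V(g)$name, name = name)
    cats <- NULL
    if ("category" %in% igraph::vertex_attr_names(g)) {
        cats <- structure(
            factor(igraph::V(g)$category, levels = NODE_CATEGORIES),
            names = toupper(igraph::V(g)$name))
        cats <- cats[net@nodes]
    }
    list(network = net, categories = cats)
}
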