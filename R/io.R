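# Plain-text file formats: expression matrices (TSV/CSV, first column gene
# id, header row of time labels), association networks (edge-list TSV,
# GraphML via igraph, SIF), complex tables, and JSON stats reports.
# Parsing is line-based so that malformed input can be reported with
# row/column coordinates.

.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix from TSV/CSV
#'
#' First column = gene identifier, header row = time labels, remaining
#' cells numeric. The delimiter is auto-detected from the extension
#' (`.csv` comma, otherwise tab) unless given. Duplicate gene ids, ragged
#' rows, and non-numeric cells are reported with their coordinates.
#'
#' @param path File path.
#' @param sep Field delimiter; default auto-detected.
#' @return Numeric matrix, gene ids as rownames, time labels as colnames.
#' @export
read_expression <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- .delim_for(path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("expression file needs a header and >= 1 gene row")
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1]]
  n_col <- length(header)
  time_labels <- trimws(header[-1])
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != n_col)) {
    bad <- which(widths != n_col)[1]
    stop(sprintf("ragged row at line %d: %d fields, expected %d",
                 bad + 1L, widths[bad], n_col))
  }
  ids <- trimws(vapply(body, `[[`, "", 1L))
  if (anyDuplicated(ids)) {
    stop("duplicate gene id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- matrix(NA_real_, length(body), n_col - 1L,
                 dimnames = list(ids, time_labels))
  for (r in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[r]][-1]))
    if (any(is.na(v))) {
      cc <- which(is.na(v))[1]
      stop(sprintf("non-numeric cell at line %d, column %d (gene %s): '%s'",
                   r + 1L, cc + 1L, ids[r], body[[r]][cc + 1L]))
    }
    vals[r, ] <- v
  }
  .check_expr(vals)
}

#' Write an expression matrix to TSV/CSV
#'
#' @param m Numeric matrix (genes x time points).
#' @param path Output path; delimiter auto-detected from the extension.
#' @param sep Optional explicit delimiter.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, sep = NULL) {
  m <- .check_expr(m)
  if (is.null(sep)) sep <- .delim_for(path)
  if (is.null(colnames(m))) colnames(m) <- paste0("t", seq_len(ncol(m)))
  header <- paste(c("gene", colnames(m)), collapse = sep)
  rows <- vapply(seq_len(nrow(m)), function(r) {
    paste(c(rownames(m)[r], format(m[r, ], trim = TRUE, digits = 15)),
          collapse = sep)
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

.net_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("edgelist", "graphml", "sif")))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         graphml = "graphml",
         sif = "sif",
         tsv = "edgelist",
         txt = "edgelist",
         stop("unknown network file extension: .", ext,
              " (use edgelist .tsv, .graphml, or .sif)"))
}

#' Write an association network
#'
#' Formats: weighted edge-list TSV (`geneA geneB weight`), GraphML
#' (via igraph, weights kept), or SIF (`geneA pp geneB`). Writing an
#' empty network is an error.
#'
#' @param a An `assoc_network`.
#' @param path Output path.
#' @param format `"edgelist"`, `"graphml"`, or `"sif"`; default inferred
#'   from the extension.
#' @return `path`, invisibly.
#' @export
write_network <- function(a, path, format = NULL) {
  stopifnot(inherits(a, "assoc_network"))
  fmt <- .net_format(path, format)
  edges <- network_edges(a)
  if (nrow(edges) == 0) stop("refusing to write an empty network")
  if (fmt == "edgelist") {
    header <- paste(c("geneA", "geneB", "weight"), collapse = "\t")
    rows <- sprintf("%s\t%s\t%.12g", edges$geneA, edges$geneB, edges$weight)
    writeLines(c(header, rows), path)
  } else if (fmt == "sif") {
    writeLines(sprintf("%s pp %s", edges$geneA, edges$geneB), path)
  } else {
    igraph::write_graph(as_igraph(a), path, format = "graphml")
  }
  invisible(path)
}

#' Read a network file
#'
#' @param path Path to an edge-list TSV, GraphML, or SIF file.
#' @param format Override the extension-based format detection.
#' @return An undirected `igraph` graph; edge-list and GraphML inputs
#'   carry a `weight` edge attribute.
#' @export
read_network <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- .net_format(path, format)
  if (fmt == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (fmt == "sif") {
    parts <- strsplit(lines, "[ \t]+")
    bad <- which(lengths(parts) != 3)
    if (length(bad)) stop("malformed SIF line ", bad[1])
    el <- do.call(rbind, lapply(parts, function(p) p[c(1, 3)]))
    return(igraph::graph_from_edgelist(el, directed = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (length(parts) && identical(parts[[1]][1], "geneA")) parts <- parts[-1]
  bad <- which(lengths(parts) < 3)
  if (length(bad)) stop("malformed edge-list line ", bad[1])
  el <- do.call(rbind, lapply(parts, function(p) p[1:2]))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$weight <- as.numeric(vapply(parts, `[[`, "", 3L))
  g
}
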