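# Undirected association networks built from directed causality strengths.
# Directionality is deliberately discarded: the aim is an association
# matrix for clustering, not a reconstructed causal wiring diagram.

#' Symmetrize a directed strength matrix into an association network
#'
#' The association weight of an unordered pair is the larger of the two
#' directional causality values, `w(i, j) = max(d(i, j), d(j, i))`; pairs
#' where neither direction passed the test keep weight 0 (no edge).
#'
#' @param d Square non-negative matrix (e.g. from [pairwise_causality()]).
#' @return An `assoc_network`: symmetric non-negative matrix with zero
#'   diagonal, row/column names preserved, `threshold` attribute NULL.
#' @export
symmetrize_max <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("input must be a square matrix")
  }
  if (any(d < 0)) stop("directed strengths must be non-negative")
  w <- pmax(unclass(d), t(unclass(d)))
  diag(w) <- 0
  if (is.null(rownames(w))) {
    dimnames(w) <- list(paste0("g", seq_len(nrow(w))),
                        paste0("g", seq_len(nrow(w))))
  }
  structure(w, threshold = NULL, class = c("assoc_network", "matrix", "array"))
}

#' Keep only the dominant edges of an association network
#'
#' Computes the empirical `q`-quantile (linear interpolation between
#' order statistics) of the *positive* edge weights and zeroes every edge
#' strictly below it; ties at the cutoff are retained. Quantiles are taken
#' over existing edges only — the structural zeros of pairs that failed
#' the causality test are not part of the edge-value population. Nodes are
#' left in place, so isolated nodes are permitted. Conventional choices:
#' `q = 0.975` for networks of tens of genes, `q = 0.99` for thousands.
#'
#' @param a An `assoc_network` from [symmetrize_max()].
#' @param q Quantile in (0, 1).
#' @return The thresholded `assoc_network`; attribute `threshold` records
#'   `list(q, cutoff)`.
#' @export
threshold_quantile <- function(a, q) {
  stopifnot(inherits(a, "assoc_network"), q > 0, q < 1)
  w <- unclass(a)
  pos <- w[upper.tri(w)]
  pos <- pos[pos > 0]
  if (length(pos) == 0) stop("no edges to threshold: network has no positive weights")
  cutoff <- unname(stats::quantile(pos, q, type = 7))
  w[w < cutoff] <- 0
  structure(w, threshold = list(q = q, cutoff = cutoff),
            class = c("assoc_network", "matrix", "array"))
}

#' @export
print.assoc_network <- function(x, ...) {
  w <- unclass(x)
  ne <- sum(w[upper.tri(w)] > 0)
  thr <- attr(x, "threshold")
  cat(sprintf("Association network: %d genes, %d edges%s\n", nrow(w), ne,
              if (is.null(thr)) ""
              else sprintf(" (thresholded at q = %g, cutoff = %.4g)",
                           thr$q, thr$cutoff)))
  invisible(x)
}

#' Edge list view of an association network
#'
#' @param a An `assoc_network`.
#' @return Data frame `geneA`, `geneB`, `weight` for each positive edge,
#'   ordered by decreasing weight.
#' @export
network_edges <- function(a) {
  stopifnot(inherits(a, "assoc_network"))
  w <- unclass(a)
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  out <- data.frame(geneA = rownames(w)[ut[, 1]],
                    geneB = colnames(w)[ut[, 2]],
                    weight = w[ut])
  out[order(-out$weight, out$geneA, out$geneB), , drop = FALSE]
}

#' Convert an association network to an igraph graph
#'
#' Only the topology (positive weights) is carried over; weights are kept
#' as the `weight` edge attribute for export but the dense-region finder
#' ignores them.
#'
#' @param a An `assoc_network`.
#' @param drop_isolated Drop zero-degree vertices? Default FALSE.
#' @return An undirected `igraph` graph with named vertices.
#' @export
as_igraph <- function(a, drop_isolated = FALSE) {
  stopifnot(inherits(a, "assoc_network"))
  g <- igraph::graph_from_adjacency_matrix(unclass(a), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (drop_isolated) {
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  }
  g
}

#' Pearson correlation baseline
#'
#' The static-similarity baseline: correlation over time points for every
#' gene pair. Time ordering plays no role, which is exactly why this
#' baseline fails on systems coupled through temporal lags.
#'
#' @param m Numeric expression matrix (genes x time).
#' @return Symmetric correlation matrix with unit diagonal; zero-variance
#'   rows produce NA entries with a warning.
#' @export
correlation_matrix <- function(m) {
  m <- .check_expr(m)
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) {
    warning("zero-variance rows yield undefined correlations: ",
            paste(rownames(m)[v == 0], collapse = ", "))
  }
  suppressWarnings(stats::cor(t(m)))
}

#' Euclidean distance baseline
#'
#' @param m Numeric expression matrix (genes x time).
#' @return Symmetric pairwise Euclidean distance matrix, zero diagonal.
#' @export
euclidean_matrix <- function(m) {
  m <- .check_expr(m)
  as.matrix(stats::dist(m))
}
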