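# Structural statistics used to distinguish an inferred association network
# from a random graph: degree distribution, shared-neighbour distribution,
# closeness centrality, topological coefficient, and small-world summaries.
# Neighbour counting and the topological coefficient are computed directly
# from the adjacency matrix so that the brute-force oracles in the test
# suite remain an independent route.

#' Degree distribution
#'
#' The probability `p(k)` that a vertex interacts with exactly `k` others.
#'
#' @param g An undirected `igraph` graph (or `assoc_network`).
#' @return Named numeric vector: names are degrees, values sum to 1.
#' @export
degree_distribution_pk <- function(g) {
  g <- .as_graph(g)
  deg <- igraph::degree(g)
  tab <- table(deg)
  pk <- as.numeric(tab) / length(deg)
  names(pk) <- names(tab)
  pk
}

#' Shared-neighbour distribution
#'
#' For every unordered vertex pair `(i, j)`, `P(i, j)` counts the common
#' neighbours of `i` and `j`; the distribution reports how many pairs
#' share `k` partners for `k = 1, 2, 3, ...` (pairs sharing none are not
#' tabulated).
#'
#' @param g An undirected `igraph` graph (or `assoc_network`).
#' @return Named integer vector: names are `k`, values are pair counts.
#' @export
shared_neighbor_distribution <- function(g) {
  g <- .as_graph(g)
  n <- igraph::vcount(g)
  if (n < 2) return(structure(integer(), names = character()))
  A <- .adjacency(g)
  CN <- A %*% A                    # (i, j) entry = common neighbours
  counts <- CN[upper.tri(CN)]
  counts <- counts[counts >= 1]
  tab <- table(counts)
  structure(as.integer(tab), names = names(tab))
}

#' Closeness centrality
#'
#' `C(v) = 1 / mean(L(v, u))` over the vertices `u != v` *reachable* from
#' `v`; isolated vertices score 0. With unit edge lengths, `C` lies in
#' `[0, 1]` and equals 1 only for a vertex adjacent to everything it can
#' reach.
#'
#' @param g An undirected `igraph` graph (or `assoc_network`).
#' @return Named numeric vector of per-vertex closeness values.
#' @export
closeness_centrality <- function(g) {
  g <- .as_graph(g)
  n <- igraph::vcount(g)
  out <- numeric(n)
  names(out) <- igraph::V(g)$name
  if (n == 0) return(out)
  D <- igraph::distances(g, weights = NA)   # hop counts, not edge weights
  for (v in seq_len(n)) {
    d <- D[v, -v]
    d <- d[is.finite(d)]
    out[v] <- if (length(d) == 0) 0 else 1 / mean(d)
  }
  out
}

#' Topological coefficient
#'
#' For a vertex `v` of degree `k_v >= 2`, average `J(v, j) / k_v` over all
#' vertices `j != v` sharing at least one neighbour with `v`, where
#' `J(v, j)` is the number of common neighbours plus 1 if `v` and `j` are
#' directly linked. Vertices of degree < 2 or with no sharing partner get
#' TC 0 and are excluded from the per-degree averages. A decreasing
#' `TC(k)` trend indicates that hubs do not share disproportionately many
#' partners — a signature of modular rather than artificially clustered
#' organisation.
#'
#' @param g An undirected `igraph` graph (or `assoc_network`).
#' @return List with `tc` (named per-vertex coefficients) and `tc_k`
#'   (named per-degree means over eligible vertices).
#' @export
topological_coefficient <- function(g) {
  g <- .as_graph(g)
  n <- igraph::vcount(g)
  tc <- numeric(n)
  names(tc) <- igraph::V(g)$name
  if (n == 0) return(list(tc = tc, tc_k = numeric()))
  A <- .adjacency(g)
  CN <- A %*% A
  deg <- rowSums(A)
  eligible <- logical(n)
  for (v in seq_len(n)) {
    if (deg[v] < 2) next
    partners <- which(CN[v, ] > 0)
    partners <- partners[partners != v]
    if (length(partners) == 0) next
    J <- CN[v, partners] + A[v, partners]
    tc[v] <- mean(J) / deg[v]
    eligible[v] <- TRUE
  }
  ks <- sort(unique(deg[eligible]))
  tc_k <- vapply(ks, function(k) mean(tc[eligible & deg == k]), 0)
  names(tc_k) <- ks
  list(tc = tc, tc_k = tc_k)
}

.adjacency <- function(g) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  diag(A) <- 0
  A
}

#' Network summary statistics
#'
#' Assembles the statistics used to characterise an association network:
#' size, sparsity (on the directed-edge scale, `2|E| / n(n-1)`), number of
#' connected components, mean shortest path length and diameter over
#' *connected* vertex pairs, and the full degree / shared-neighbour /
#' closeness / topological-coefficient profiles. An edgeless graph
#' reports 0 path statistics with `has_paths = FALSE`.
#'
#' @param g An undirected `igraph` graph (or `assoc_network`).
#' @return A `network_stats` list.
#' @export
network_summary <- function(g) {
  g <- .as_graph(g)
  n <- igraph::vcount(g)
  ne <- igraph::ecount(g)
  comp <- igraph::components(g)
  if (ne > 0) {
    D <- igraph::distances(g, weights = NA)   # hop counts, not edge weights
    d <- D[upper.tri(D)]
    d <- d[is.finite(d) & d > 0]
    mean_path <- mean(d)
    diameter <- max(d)
    has_paths <- TRUE
  } else {
    mean_path <- 0; diameter <- 0; has_paths <- FALSE
  }
  structure(list(
    n_nodes = n,
    n_edges = ne,
    sparsity = if (n > 1) 2 * ne / (n * (n - 1)) else 0,
    n_components = comp$no,
    mean_shortest_path = mean_path,
    diameter = diameter,
    has_paths = has_paths,
    degree_distribution = degree_distribution_pk(g),
    shared_neighbors = shared_neighbor_distribution(g),
    closeness = closeness_centrality(g),
    topological = topological_coefficient(g)
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "Network statistics\n",
    "  nodes: %d, edges: %d, sparsity: %.4g\n",
    "  components: %d\n",
    "  mean shortest path: %.3g, diameter: %g%s\n"),
    x$n_nodes, x$n_edges, x$sparsity, x$n_components,
    x$mean_shortest_path, x$diameter,
    if (x$has_paths) "" else " (no connected pairs)"))
  invisible(x)
}
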