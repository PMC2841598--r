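# Dense-region ("molecular complex") detection in the association graph.
# The algorithm is purely topological: vertices are weighted by the k-core
# structure of their closed neighbourhood, complexes are grown greedily from
# high-weight seeds, and results are filtered (2-core), trimmed (haircut),
# and ranked by density x size.
#
# k-core peeling, vertex weighting, and expansion are implemented here from
# first principles (they are the object under test); igraph supplies only
# the graph container and induced subgraphs.

.as_graph <- function(g) {
  if (inherits(g, "assoc_network")) g <- as_igraph(g)
  if (!igraph::is_igraph(g)) stop("expected an igraph graph or assoc_network")
  if (igraph::is_directed(g)) stop("graph must be undirected")
  if (is.null(igraph::V(g)$name)) {
    g <- igraph::set_vertex_attr(g, "name",
                                 value = paste0("v", seq_len(igraph::vcount(g))))
  }
  g
}

#' Graph density
#'
#' `|E|` divided by the `|V|(|V|-1)/2` edges of the complete graph on the
#' same vertices. Graphs with fewer than two vertices have density 0 (with
#' a warning): there is no possible edge to be present.
#'
#' @param g An undirected `igraph` graph (or `assoc_network`).
#' @return Density in `[0, 1]`.
#' @export
graph_density <- function(g) {
  g <- .as_graph(g)
  n <- igraph::vcount(g)
  if (n < 2) {
    warning("density undefined for |V| < 2; returning 0")
    return(0)
  }
  igraph::ecount(g) / (n * (n - 1) / 2)
}

#' k-core of a graph
#'
#' The maximal subgraph in which every vertex has degree at least `k`,
#' computed by iteratively peeling under-degree vertices. May be empty.
#'
#' @param g An undirected `igraph` graph (or `assoc_network`).
#' @param k Minimum degree (>= 0).
#' @return The core as an induced `igraph` subgraph (possibly with 0
#'   vertices).
#' @export
k_core <- function(g, k) {
  g <- .as_graph(g)
  k <- as.integer(k)
  stopifnot(k >= 0L)
  repeat {
    if (igraph::vcount(g) == 0) return(g)
    low <- which(igraph::degree(g) < k)
    if (length(low) == 0) return(g)
    g <- igraph::delete_vertices(g, low)
  }
}

#' Highest k-core of a graph
#'
#' The non-empty core with the largest `k` — the central, most densely
#' interconnected region of the graph.
#'
#' @param g An undirected `igraph` graph (or `assoc_network`).
#' @return List with `core` (igraph subgraph) and `k_max` (0 for an
#'   edgeless or empty graph, where the 0-core is the graph itself).
#' @export
highest_k_core <- function(g) {
  g <- .as_graph(g)
  if (igraph::vcount(g) == 0) return(list(core = g, k_max = 0L))
  core <- g
  k_max <- 0L
  k <- 1L
  repeat {
    nxt <- k_core(core, k)   # cores are nested: peel the previous core
    if (igraph::vcount(nxt) == 0) break
    core <- nxt
    k_max <- k
    k <- k + 1L
  }
  list(core = core, k_max = k_max)
}

#' Local-density vertex weights
#'
#' Each vertex is scored by the highest k-core of its *closed*
#' neighbourhood (the vertex plus its neighbours, with induced edges):
#' `weight(v) = k_max x density(core)`. This amplifies vertices sitting
#' inside densely interconnected regions while zeroing isolated vertices,
#' and provides the seed ranking for [find_complexes()].
#'
#' @param g An undirected `igraph` graph (or `assoc_network`).
#' @return Named numeric vector of weights (one per vertex).
#' @export
vertex_weights <- function(g) {
  g <- .as_graph(g)
  n <- igraph::vcount(g)
  w <- numeric(n)
  names(w) <- igraph::V(g)$name
  if (n == 0) return(w)
  for (v in seq_len(n)) {
    nb <- igraph::neighbors(g, v)
    if (length(nb) == 0) next               # isolated vertex: weight 0
    sub <- igraph::induced_subgraph(g, c(v, as.integer(nb)))
    hk <- highest_k_core(sub)
    dens <- if (igraph::vcount(hk$core) >= 2) {
      suppressWarnings(graph_density(hk$core))
    } else 0
    w[v] <- hk$k_max * dens
  }
  w
}

#' Score of a complex
#'
#' Density of the induced subgraph times the number of vertices,
#' `D_c x |V_c|` — rewards subgraphs that are simultaneously dense and
#' large. A singleton scores 0 with a warning.
#'
#' @param g An undirected `igraph` subgraph (or `assoc_network`), or a
#'   `complex` object.
#' @return Non-negative score.
#' @export
score_complex <- function(g) {
  if (inherits(g, "gene_complex")) g <- g$graph
  g <- .as_graph(g)
  n <- igraph::vcount(g)
  if (n < 2) {
    warning("singleton complex scores 0")
    return(0)
  }
  graph_density(g) * n
}

#' Detect dense regions (complexes) in a graph
#'
#' Greedy seeded expansion over [vertex_weights()]: the highest-weight
#' unseen vertex seeds a complex, and the frontier recursively absorbs
#' neighbours whose weight exceeds `(1 - vwp)` times the seed weight.
#' Each vertex joins at most one complex. Post-processing drops complexes
#' lacking a k-core of `min_core` (default 2: tree-like regions are never
#' reported) and, with `haircut`, iteratively trims degree-1 vertices from
#' each surviving complex. Complexes are ranked by score (density x size)
#' descending, ties by size descending then seed id; all internal
#' tie-breaks use the stable vertex order, so output is deterministic.
#'
#' @param g An undirected `igraph` graph or `assoc_network` (edge weights
#'   ignored: topology only).
#' @param vwp Vertex weight percentage in `[0, 1)`: expansion threshold
#'   fraction below the seed weight. Default 0.2.
#' @param haircut Trim degree-1 vertices from each complex? Default TRUE.
#' @param min_core Post-filter core level, default 2.
#' @return A `complex_list`: list of `complex` objects, each with
#'   `members` (vertex names), `n`, `density`, `score`, `seed`, `rank`,
#'   `graph` (induced igraph subgraph).
#' @export
find_complexes <- function(g, vwp = 0.2, haircut = TRUE, min_core = 2L) {
  stopifnot(vwp >= 0, vwp < 1, min_core >= 0)
  g <- .as_graph(g)
  n <- igraph::vcount(g)
  out <- list()
  if (n > 0) {
    w <- vertex_weights(g)
    nbrs <- igraph::adjacent_vertices(g, seq_len(n))
    seen <- logical(n)
    # stable seed order: weight descending, vertex name ascending on ties
    order_idx <- order(-w, igraph::V(g)$name)
    for (seed in order_idx) {
      if (seen[seed] || w[seed] <= 0) next
      thr <- (1 - vwp) * w[seed]
      members <- seed
      seen[seed] <- TRUE
      queue <- seed
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        for (u in as.integer(nbrs[[v]])) {
          if (!seen[u] && w[u] > thr) {
            seen[u] <- TRUE
            members <- c(members, u)
            queue <- c(queue, u)
          }
        }
      }
      sub <- igraph::induced_subgraph(g, sort(members))
      if (igraph::vcount(k_core(sub, min_core)) == 0) next
      if (haircut) {
        repeat {
          deg1 <- which(igraph::degree(sub) < 2)
          if (length(deg1) == 0) break
          sub <- igraph::delete_vertices(sub, deg1)
        }
        if (igraph::vcount(sub) == 0) next
      }
      out[[length(out) + 1L]] <- list(
        members = sort(igraph::V(sub)$name),
        n = as.integer(igraph::vcount(sub)),
        density = suppressWarnings(graph_density(sub)),
        score = suppressWarnings(score_complex(sub)),
        seed = igraph::V(g)$name[seed],
        graph = sub)
    }
  }
  if (length(out)) {
    ord <- order(-vapply(out, `[[`, 0, "score"),
                 -vapply(out, `[[`, 0L, "n"),
                 vapply(out, `[[`, "", "seed"))
    out <- out[ord]
    for (r in seq_along(out)) {
      out[[r]]$rank <- r
      class(out[[r]]) <- "gene_complex"
    }
  }
  structure(out, class = "complex_list")
}

#' @export
print.complex_list <- function(x, ...) {
  cat(sprintf("%d complex(es) detected\n", length(x)))
  for (cc in x) {
    cat(sprintf("  #%d score %.3f (%d vertices, density %.3f, seed %s): %s\n",
                cc$rank, cc$score, cc$n, cc$density, cc$seed,
                paste(cc$members, collapse = ", ")))
  }
  invisible(x)
}

#' Table view of a complex list
#'
#' @param x A `complex_list` from [find_complexes()].
#' @param ... Unused.
#' @return Data frame `rank`, `score`, `n_vertices`, `seed`, `members`
#'   (comma-joined vertex ids).
#' @export
as.data.frame.complex_list <- function(x, ...) {
  if (length(x) == 0) {
    return(data.frame(rank = integer(), score = numeric(),
                      n_vertices = integer(), seed = character(),
                      members = character()))
  }
  data.frame(rank = vapply(x, `[[`, 0L, "rank"),
             score = vapply(x, `[[`, 0, "score"),
             n_vertices = vapply(x, `[[`, 0L, "n"),
             seed = vapply(x, `[[`, "", "seed"),
             members = vapply(x, function(cc) paste(cc$members, collapse = ","), ""))
}
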