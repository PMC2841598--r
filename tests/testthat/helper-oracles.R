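# Graph fixtures and brute-force oracles. The oracles enumerate or loop
# naively and never share code with the implementation under test.

named_graph <- function(el, n = max(el)) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  if (length(el)) g <- igraph::add_edges(g, t(el))
  g
}

complete_graph <- function(n) named_graph(t(utils::combn(seq_len(n), 2)), n)

star_graph <- function(leaves) {
  named_graph(cbind(1L, seq_len(leaves) + 1L), leaves + 1L)
}

path_graph <- function(n) named_graph(cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L), n)

cycle_graph <- function(n) {
  named_graph(rbind(cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L), c(n, 1L)), n)
}

# two K4s joined by a single bridge edge (vertices 4 and 5)
bridged_k4s <- function() {
  el <- rbind(t(utils::combn(1:4, 2)), t(utils::combn(5:8, 2)), c(4L, 5L))
  named_graph(el, 8L)
}

random_graph <- function(n, p, seed) {
  set.seed(seed)
  full <- t(utils::combn(seq_len(n), 2))
  named_graph(full[stats::runif(nrow(full)) < p, , drop = FALSE], n)
}

adj_of <- function(g) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  diag(A) <- 0
  A
}

# k-core by subset enumeration: the union of all vertex subsets whose
# induced subgraph has minimum degree >= k (min-degree >= k is closed
# under union, so the union is the maximal such subgraph). n <= ~12.
bf_kcore_vertices <- function(A, k) {
  n <- nrow(A)
  members <- rep(FALSE, n)
  for (mask in seq_len(2^n) - 1L) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
    sz <- sum(sel)
    if (sz == 0 || sz <= k) next   # need degree >= k, so > k vertices
    degs <- rowSums(A[sel, sel, drop = FALSE])
    if (all(degs >= k)) members <- members | sel
  }
  which(members)
}

# all-pairs shortest paths by BFS
bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer()
      for (v in frontier) {
        for (u in which(A[v, ] > 0)) {
          if (dist[u] > d) { dist[u] <- d; nxt <- c(nxt, u) }
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

# shared-neighbour counts by double loop
bf_shared_counts <- function(A) {
  n <- nrow(A)
  out <- integer()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      k <- sum(A[i, ] > 0 & A[j, ] > 0)
      if (k >= 1) out <- c(out, k)
    }
  }
  out
}

# topological coefficient straight from the definition
bf_tc <- function(A) {
  n <- nrow(A)
  tc <- numeric(n)
  for (v in seq_len(n)) {
    kv <- sum(A[v, ])
    if (kv < 2) next
    vals <- numeric()
    for (j in seq_len(n)) {
      if (j == v) next
      cn <- sum(A[v, ] > 0 & A[j, ] > 0)
      if (cn >= 1) vals <- c(vals, (cn + A[v, j]) / kv)
    }
    if (length(vals)) tc[v] <- mean(vals)
  }
  tc
}

# independent OLS via explicit normal equations
bf_ols_rss <- function(X, y) {
  beta <- solve(crossprod(X), crossprod(X, y))
  sum((y - X %*% beta)^2)
}
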