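test_that("graph_density counts edges against the complete graph", {
  expect_equal(graph_density(complete_graph(4)), 1)
  tri_plus_isolate <- named_graph(rbind(c(1, 2), c(2, 3), c(1, 3)), 4)
  expect_equal(graph_density(tri_plus_isolate), 0.5)
  expect_equal(graph_density(named_graph(matrix(integer(), 0, 2), 5)), 0)
  expect_warning(d1 <- graph_density(named_graph(matrix(integer(), 0, 2), 1)),
                 "undefined")
  expect_equal(d1, 0)
})

test_that("k_core peeling matches known cores", {
  k4 <- complete_graph(4)
  expect_setequal(igraph::V(k_core(k4, 3))$name, igraph::V(k4)$name)
  # trees peel away entirely at k = 2
  tree <- named_graph(rbind(c(1, 2), c(1, 3), c(3, 4), c(3, 5)), 5)
  expect_equal(igraph::vcount(k_core(tree, 2)), 0)
  # 5-cycle with a pendant: the 2-core is the cycle
  cyc <- named_graph(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 1),
                           c(5, 6)), 6)
  expect_setequal(igraph::V(k_core(cyc, 2))$name, sprintf("v%02d", 1:5))
})

test_that("k_core equals brute-force subset enumeration on random graphs", {
  for (seed in 1:30) {
    n <- 4 + (seed %% 6)
    g <- random_graph(n, 0.4, seed)
    A <- adj_of(g)
    for (k in 0:4) {
      expect_setequal(igraph::V(k_core(g, k))$name,
                      rownames(A)[bf_kcore_vertices(A, k)])
    }
  }
})

test_that("cores are nested in k", {
  for (seed in 31:40) {
    g <- random_graph(8, 0.5, seed)
    prev <- igraph::V(k_core(g, 1))$name
    for (k in 2:5) {
      cur <- igraph::V(k_core(g, k))$name
      expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("highest_k_core finds the central subgraph", {
  k5 <- complete_graph(5)
  hk <- highest_k_core(k5)
  expect_equal(hk$k_max, 4L)
  expect_equal(igraph::vcount(hk$core), 5)
  # two triangles joined by a bridge: both triangles form the 2-core
  g <- named_graph(rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6),
                         c(4, 6), c(3, 4)), 6)
  hk2 <- highest_k_core(g)
  expect_equal(hk2$k_max, 2L)
  expect_setequal(igraph::V(hk2$core)$name, sprintf("v%02d", 1:6))
  edge <- named_graph(rbind(c(1, 2)), 2)
  hk3 <- highest_k_core(edge)
  expect_equal(hk3$k_max, 1L)
  expect_equal(highest_k_core(named_graph(matrix(integer(), 0, 2), 3))$k_max, 0L)
})

test_that("vertex weights follow k_max x core density on the closed neighborhood", {
  expect_true(all(vertex_weights(complete_graph(5)) == 4))
  # middle of a 3-path: closed neighbourhood is the path, 1-core, density 2/3
  p3 <- path_graph(3)
  w <- vertex_weights(p3)
  expect_equal(unname(w["v02"]), 2 / 3, tolerance = 1e-12)
  with_iso <- named_graph(rbind(c(1, 2)), 3)
  expect_equal(unname(vertex_weights(with_iso)["v03"]), 0)
})

test_that("find_complexes on hand-traceable fixtures", {
  # a lone K5 is one complex with score 5
  cx <- find_complexes(complete_graph(5))
  expect_length(cx, 1)
  expect_equal(cx[[1]]$score, 5)
  expect_setequal(cx[[1]]$members, sprintf("v%02d", 1:5))
  # trees have no 2-core: no complexes
  tree <- named_graph(rbind(c(1, 2), c(1, 3), c(3, 4), c(3, 5), c(5, 6)), 6)
  expect_length(find_complexes(tree), 0)
  # two K4s joined by a bridge: every vertex weighs 3 (its closed
  # neighbourhood still contains its own K4 as highest core), so the
  # greedy expansion at vwp = 0.2 crosses the bridge and returns ONE
  # complex of all 8 vertices, density 13/28, score 26/7
  cx2 <- find_complexes(bridged_k4s())
  expect_length(cx2, 1)
  expect_equal(cx2[[1]]$n, 8L)
  expect_equal(cx2[[1]]$score, 26 / 7, tolerance = 1e-12)
})

test_that("score_complex multiplies density by size", {
  expect_equal(score_complex(complete_graph(5)), 5)
  expect_equal(score_complex(cycle_graph(4)), (4 / 6) * 4)
  expect_equal(score_complex(cycle_graph(3)), 3)
  expect_warning(s <- score_complex(named_graph(matrix(integer(), 0, 2), 1)),
                 "singleton")
  expect_equal(s, 0)
})

test_that("complexes are vertex-disjoint, 2-cored, and deterministic", {
  for (seed in 41:55) {
    g <- random_graph(12, 0.35, seed)
    cx <- find_complexes(g)
    all_members <- unlist(lapply(cx, `[[`, "members"))
    expect_equal(anyDuplicated(all_members), 0L)
    for (cc in cx) {
      expect_gt(igraph::vcount(k_core(cc$graph, 2)), 0)
      expect_true(all(igraph::degree(cc$graph) >= 2))  # haircut applied
      expect_equal(cc$score, score_complex(cc$graph))
    }
    # identical reruns give identical ranked output
    cx2 <- find_complexes(g)
    expect_equal(as.data.frame(cx), as.data.frame(cx2))
    # ranking is by descending score
    scores <- vapply(cx, `[[`, 0, "score")
    expect_true(all(diff(scores) <= 1e-12))
  }
})
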