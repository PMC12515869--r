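g_from <- function(...) {
  e <- matrix(c(...), ncol = 2, byrow = TRUE)
  ppi_graph(data.frame(from = e[, 1], to = e[, 2]))
}

test_that("k-core matches iterative pruning on small and random graphs", {
  tri <- g_from("a", "b", "b", "c", "c", "a")
  expect_equal(sort(igraph::V(k_core(tri, 2))$name), c("a", "b", "c"))

  star <- g_from("h", "x", "h", "y", "h", "z")
  expect_equal(igraph::vcount(k_core(star, 2)), 0)
  expect_equal(igraph::vcount(k_core(star, 0)), 4)

  set.seed(71)
  for (i in 1:60) {
    n <- sample(3:7, 1)
    g <- random_named_graph(n, runif(1, 0.2, 0.9))
    adj <- adjacency_of(g)
    for (k in 0:4) {
      got <- sort(as.integer(igraph::V(k_core(g, k))$name))
      expect_equal(got, sort(kcore_oracle_nodes(adj, k)))
      # idempotence
      expect_equal(igraph::vcount(k_core(k_core(g, k), k)),
                   igraph::vcount(k_core(g, k)))
    }
  }
})

test_that("vertex weights equal k_max times core density", {
  k4 <- g_from("a", "b", "a", "c", "a", "d", "b", "c", "b", "d", "c", "d")
  expect_equal(unname(vertex_weights(k4)), rep(3, 4))

  path <- g_from("a", "b", "b", "c")
  w <- vertex_weights(path)
  expect_equal(unname(w["b"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(w["a"]), 1)

  iso <- igraph::add_vertices(path, 1, name = "lonely")
  expect_equal(unname(vertex_weights(iso)["lonely"]), 0)

  set.seed(72)
  for (i in 1:40) {
    g <- random_named_graph(sample(3:7, 1), runif(1, 0.2, 0.9))
    adj <- adjacency_of(g)
    got <- vertex_weights(g)
    want <- vapply(seq_len(nrow(adj)), function(v) vertex_weight_oracle(adj, v),
                   numeric(1))
    expect_equal(unname(got[as.character(seq_len(nrow(adj)))]), want,
                 tolerance = 1e-12)
  }
})

test_that("vertex weights are local and can drop when a core dilutes", {
  # a new edge can pull a low-degree neighbor into the highest core of
  # N[v], lowering that core's density: weight(x) falls from 3 to 2.7
  g1 <- g_from("x", "a", "x", "b", "x", "c", "x", "d",
               "a", "b", "a", "c", "b", "c", "d", "a")
  g2 <- igraph::add_edges(g1, c("d", "b"))
  expect_equal(unname(vertex_weights(g1)["x"]), 3)
  expect_equal(unname(vertex_weights(g2)["x"]), 2.7, tolerance = 1e-12)

  # locality: an edge with both endpoints outside N[v] never changes w(v)
  set.seed(73)
  for (i in 1:25) {
    g <- random_named_graph(8, 0.3)
    adj <- adjacency_of(g)
    w1 <- vertex_weights(g)
    absent <- which(upper.tri(adj) & adj == 0, arr.ind = TRUE)
    if (nrow(absent) == 0) next
    pick <- absent[sample.int(nrow(absent), 1), ]
    g2 <- igraph::add_edges(g, as.character(pick))
    w2 <- vertex_weights(g2)
    touched <- unique(c(pick, which(adj[pick[1], ] > 0 | adj[pick[2], ] > 0)))
    untouched <- setdiff(seq_len(nrow(adj)), touched)
    expect_equal(w2[as.character(untouched)], w1[as.character(untouched)],
                 tolerance = 1e-12)
  }
})

test_that("cluster scores are density times size", {
  k4 <- g_from("a", "b", "a", "c", "a", "d", "b", "c", "b", "d", "c", "d")
  expect_equal(cluster_score(k4, c("a", "b", "c", "d")), 4)
  expect_equal(cluster_score(k4, c("a", "b", "c")), 3)
  p4 <- g_from("a", "b", "b", "c", "c", "d")
  expect_equal(cluster_score(p4, c("a", "b", "c", "d")), 2)
  expect_error(cluster_score(k4, "a"), ">= 2")
})

test_that("MCODE resolves planted complexes and scores them", {
  k4 <- g_from("a", "b", "a", "c", "a", "d", "b", "c", "b", "d", "c", "d")
  res <- mcode_find_complexes(k4)
  expect_equal(nrow(res), 1)
  expect_equal(res$score, 4)

  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_equal(nrow(mcode_find_complexes(empty)), 0)
  edgeless <- igraph::add_vertices(empty, 3, name = c("x", "y", "z"))
  expect_equal(nrow(mcode_find_complexes(edgeless)), 0)

  # two K6 cliques joined through a linker node: 2 complexes of score 6
  cl1 <- t(combn(paste0("a", 1:6), 2))
  cl2 <- t(combn(paste0("b", 1:6), 2))
  linker <- ppi_graph(data.frame(
    from = c(cl1[, 1], cl2[, 1], "a1", "L"),
    to = c(cl1[, 2], cl2[, 2], "L", "b1")))
  res2 <- mcode_find_complexes(linker)
  expect_equal(nrow(res2), 2)
  expect_equal(res2$score, c(6, 6))
  expect_setequal(strsplit(res2$members[1], ";")[[1]], paste0("a", 1:6))

  # direct bridge edge: uniform weights let the expansion cross, one
  # merged complex of 12 nodes and 31 edges -> score 2*31/(12*11)*12
  bridge <- ppi_graph(data.frame(
    from = c(cl1[, 1], cl2[, 1], "a1"),
    to = c(cl1[, 2], cl2[, 2], "b1")))
  res3 <- mcode_find_complexes(bridge)
  expect_equal(nrow(res3), 1)
  expect_equal(res3$n_members, 12)
  expect_equal(res3$score, 2 * 31 / (12 * 11) * 12, tolerance = 1e-12)
})

test_that("planted-partition blocks are recovered when separable", {
  g <- generate_ppi_graph(50, rep(list(c(15, 0.9)), 3), p_out = 0, seed = 1)
  res <- mcode_find_complexes(g)
  planted <- split(igraph::V(g)$name, igraph::V(g)$planted)
  planted <- planted[names(planted) != "0"]
  found <- strsplit(res$members, ";")
  jac <- vapply(planted, function(p) {
    max(vapply(found, function(m)
      length(intersect(p, m)) / length(unique(c(p, m))), numeric(1)))
  }, numeric(1))
  expect_true(all(jac >= 0.8))
})

test_that("edge-list loading rejects malformed graphs and filters scores", {
  expect_error(ppi_graph(data.frame(from = "a", to = "a")), "self-loop")
  expect_error(ppi_graph(data.frame(from = c("a", "b"), to = c("b", "a"))),
               "duplicate")
  df <- data.frame(from = c("a", "b"), to = c("b", "c"), score = c(0.9, 0.2))
  expect_equal(igraph::ecount(ppi_graph(df, min_score = 0.5)), 1)
})
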