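test_that("edge correctness follows its definition and conventions", {
  g <- random_graph(8, 0.4, seed = 21)
  idmap <- setNames(g$nodes$node_id, as.character(g$nodes$node_id))
  expect_equal(edge_correctness(g, g, idmap), 1)

  star <- toy_graph(data.frame(from = c(1, 1), to = c(2, 3)))
  p3 <- path_graph(3)
  expect_equal(edge_correctness(star, p3, c("1" = 1L, "2" = 2L, "3" = 3L)),
               0.5)
  tri <- toy_graph(data.frame(from = c(1, 1, 2), to = c(2, 3, 3)))
  expect_equal(edge_correctness(p3, tri, c("1" = 3L, "2" = 1L, "3" = 2L)), 1)

  nf <- pathway_graph(data.frame(node_id = 1:2, node_class = "gene"))
  expect_warning(ec <- edge_correctness(nf, tri, c("1" = 1L, "2" = 2L)),
                 "convention")
  expect_equal(ec, 1)
  expect_error(edge_correctness(p3, tri, c("1" = 1L, "2" = 1L, "3" = 2L)),
               "injective")
  expect_error(edge_correctness(p3, tri, c("1" = 1L)), "total")
})

test_that("edge correctness equals the naive per-edge loop on random inputs", {
  set.seed(422)
  for (r in 1:60) {
    nG <- sample(2:8, 1); nH <- sample(nG:10, 1)
    G <- random_graph(nG, runif(1, 0.2, 0.8), seed = sample.int(1e6, 1))
    H <- random_graph(nH, runif(1, 0.2, 0.8), seed = sample.int(1e6, 1))
    if (nrow(G$edges) == 0) next
    mp <- setNames(sample(H$nodes$node_id, nG), as.character(G$nodes$node_id))
    expect_equal(edge_correctness(G, H, mp), oracle_edge_correctness(G, H, mp))
  }
})

test_that("alignment embeds small graphs sensibly", {
  p3 <- path_graph(3)
  al <- align_graphs(p3, p3, alpha = 0.8)
  expect_equal(al$edge_correctness, 1)
  expect_false(anyDuplicated(al$mapping) > 0)

  tri <- toy_graph(data.frame(from = c(1, 1, 2), to = c(2, 3, 3)),
                   species = "tri")
  e1 <- toy_graph(data.frame(from = 1, to = 2), species = "e")
  expect_equal(align_graphs(e1, tri)$edge_correctness, 1)

  single <- pathway_graph(data.frame(node_id = 1, node_class = "gene"),
                          species = "s1")
  expect_warning(al1 <- align_graphs(single, tri), "convention")
  expect_length(al1$mapping, 1)
  expect_error(align_graphs(pathway_graph(NULL), tri), "empty")
  expect_error(align_graphs(tri, e1), "more nodes")
})

test_that("pathway distance is symmetric and 1 - EC", {
  g <- random_connected_graph(8, 0.35, seed = 31, species = "a")
  h <- random_connected_graph(11, 0.3, seed = 32, species = "b")
  d1 <- pathway_distance(g, h)
  expect_equal(d1, pathway_distance(h, g))
  al <- align_graphs(g, h)
  expect_equal(d1, 1 - al$edge_correctness)
  expect_equal(pathway_distance(g, g), 0)

  e1 <- toy_graph(data.frame(from = 1, to = 2), species = "x")
  k4 <- toy_graph(expand.grid(from = 1:4, to = 1:4), species = "y")
  expect_equal(pathway_distance(e1, k4), 0)

  D <- pathway_distance_matrix(list(g, h))
  expect_equal(D["a", "b"], d1)
  expect_equal(diag(D), c(a = 0, b = 0))
})

test_that("disconnected smaller graphs are aligned component-wise", {
  G <- toy_graph(data.frame(from = c(1, 4), to = c(2, 5)), n = 5,
                 species = "disc")
  H <- random_connected_graph(9, 0.4, seed = 51, species = "big")
  al <- align_graphs(G, H)
  expect_length(al$mapping, 5)
  expect_false(anyNA(al$mapping))
  expect_false(anyDuplicated(al$mapping) > 0)
})
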