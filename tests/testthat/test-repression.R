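test_that("single-edge repression matches the hand computation", {
  g <- tiny_graph("A", "B")
  m <- node_repression(g, c(A = 1, B = 1), "B")
  # before: s_A = s_B = ln(1/2); after removing B: A isolated, s_A = 0
  expect_equal(unname(m$delta_S["B"]), 2 * log(1 / 2), tolerance = 1e-12)
  M <- as.matrix(m$matrix)
  expect_equal(M["A", "B"], log(1 / 2), tolerance = 1e-12)
  expect_equal(M["B", "B"], log(1 / 2), tolerance = 1e-12)
})

test_that("repressing an isolated node has no structural effect", {
  g <- tiny_graph("A", "B")
  g <- igraph::add_vertices(g, 1, name = "D")
  m <- node_repression(g, c(A = 1, B = 1, D = 4), "D")
  expect_equal(unname(m$delta_S["D"]), 0)
  expect_true(all(as.matrix(m$matrix) == 0))
})

test_that("sparsity pattern touches only the target and its neighbours", {
  rg <- random_test_graph(20, 0.2, 77)$graph
  w <- make_expression(rg, rng_seed = 77)
  targets <- igraph::V(rg)$name[1:5]
  m <- node_repression(rg, w, targets)
  tr <- Matrix::summary(m$matrix)
  for (k in seq_len(nrow(tr))) {
    row_node <- m$nodes[tr$i[k]]
    col_node <- m$targets[tr$j[k]]
    nbrs <- names(igraph::neighbors(rg, col_node))
    expect_true(row_node == col_node || row_node %in% nbrs)
  }
})

test_that("incremental recomputation equals the full-recompute oracle", {
  for (s in 1:20) {
    n <- 10 + (s %% 21)
    rg <- random_test_graph(n, 0.2, s + 300)$graph
    w <- make_expression(rg, rng_seed = s)
    m <- node_repression(rg, w)
    M <- as.matrix(m$matrix)
    for (tgt in m$targets) {
      oracle <- repression_oracle(rg, w, tgt)
      expect_equal(M[, tgt], oracle$column, tolerance = 1e-12)
      expect_equal(unname(m$delta_S[tgt]), oracle$delta_S, tolerance = 1e-12)
    }
  }
})

test_that("column sums equal delta_S by construction", {
  rg <- random_test_graph(25, 0.15, 88)$graph
  w <- make_expression(rg, rng_seed = 88)
  m <- node_repression(rg, w)
  expect_equal(unname(Matrix::colSums(m$matrix)), unname(m$delta_S))
})

test_that("node_repression validates targets, weights and state function", {
  g <- tiny_graph("A", "B")
  expect_error(node_repression(g, c(A = 1, B = 1), "Z"), "Z")
  expect_error(node_repression(g, c(A = 1), "B"), "B")
  expect_error(node_repression(g, c(A = 1, B = 1), "B",
                               state_function = "degree"),
               "network_potential")
  expect_error(node_repression(g, c(A = 1, B = 1), character(0)), "no targets")
})

test_that("rank_targets orders by |delta_S| with id tie-breaks", {
  g <- tiny_graph("A", "B", "B", "C", "C", "D")
  w <- c(A = 1, B = 5, C = 2, D = 1)
  m <- node_repression(g, w)
  r <- rank_targets(m)
  expect_setequal(r$node, igraph::V(g)$name)       # permutation, no drops
  expect_equal(anyDuplicated(r$node), 0)
  expect_true(all(diff(abs(r$delta_S)) <= 1e-15))
  # magnitude ties break by node id ascending
  fake <- m
  fake$delta_S <- c(A = 2, B = -2, C = 1, D = 1)
  fake$targets <- c("A", "B", "C", "D")
  r2 <- rank_targets(fake)
  expect_equal(r2$node, c("A", "B", "C", "D"))
})

test_that("degree-preserving rewiring keeps every degree and is seeded", {
  for (s in 1:20) {
    rg <- random_test_graph(30, 0.15, s + 500)$graph
    rw <- rewire_preserving_degrees(rg, swap_multiplier = 10, rng_seed = s)
    expect_equal(igraph::degree(rw)[igraph::V(rg)$name],
                 igraph::degree(rg)[igraph::V(rg)$name])
  }
  rg <- random_test_graph(30, 0.15, 600)$graph
  a <- rewire_preserving_degrees(rg, rng_seed = 4)
  b <- rewire_preserving_degrees(rg, rng_seed = 4)
  expect_true(identical_graphs(a, b))
})

test_that("graphs admitting no valid swap come back unchanged", {
  tri <- tiny_graph("A", "B", "B", "C", "C", "A")
  rw <- rewire_preserving_degrees(tri, rng_seed = 1)
  expect_true(identical_graphs(rw, tri))
  single <- tiny_graph("A", "B")
  expect_warning(rw1 <- rewire_preserving_degrees(single, rng_seed = 1),
                 "fewer than two edges")
  expect_true(identical_graphs(rw1, single))
})

test_that("rewired-graph null concentrates p near 1 on a regular graph", {
  # equal weights + regular topology: rewiring cannot change any
  # neighbourhood sum, so |delta_S_null| always ties |delta_S_obs|
  ring <- make_graph("ring", 12)
  w <- rep(2, 12)
  names(w) <- igraph::V(ring)$name
  nd <- compute_null_dnp(ring, w, n_rewires = 5, rng_seed = 3)
  expect_true(all(nd$p_value == 1))
  expect_true(all(nd$p_value >= 1 / 6))
  expect_error(compute_null_dnp(ring, w, n_rewires = 0), "at least 1")
})

test_that("null p-values land on the add-one grid and are reproducible", {
  rg <- random_test_graph(16, 0.25, 901)$graph
  w <- make_expression(rg, rng_seed = 901)
  targets <- igraph::V(rg)$name[1:4]
  nd <- compute_null_dnp(rg, w, targets, n_rewires = 9, rng_seed = 11)
  expect_true(all(nd$p_value %in% ((1:10) / 10)))
  nd2 <- compute_null_dnp(rg, w, targets, n_rewires = 9, rng_seed = 11)
  expect_identical(nd, nd2)
})

test_that("repression matrices serialise to triplets plus ranked summary", {
  g <- tiny_graph("A", "B")
  m <- node_repression(g, c(A = 1, B = 1), "B")
  stem <- tempfile()
  write_repression(m, stem)
  trip <- utils::read.delim(paste0(stem, "_triplets.tsv"))
  expect_identical(names(trip), c("row_node", "col_node", "delta"))
  summ <- utils::read.delim(paste0(stem, "_summary.tsv"))
  expect_equal(summ$delta_S[summ$node == "B"], 2 * log(1 / 2),
               tolerance = 1e-10)
})
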