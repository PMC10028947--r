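# A "double star": two hubs of equal degree, each with its own leaves, so the
# hub seed always has a degree-matched null candidate.
double_star <- function(k = 5) {
  edges <- rbind(cbind("H1", sprintf("L%02d", 1:k)),
                 cbind("H2", sprintf("M%02d", 1:k)))
  build_graph(data.frame(a = edges[, 1], b = edges[, 2]))
}

test_that("null seeds are degree-matched, exclude observed seeds, reproducible", {
  ring <- make_graph("ring", 8)   # regular graph: one bin
  sets <- sample_null_seeds(ring, "G0003", n_bootstrap = 3, rng_seed = 42)
  expect_length(sets, 3)
  for (s in sets) {
    expect_length(s, 1)
    expect_false(s == "G0003")
    expect_true(s %in% igraph::V(ring)$name)
  }
  expect_identical(sets, sample_null_seeds(ring, "G0003", 3, rng_seed = 42))
  expect_false(identical(sets, sample_null_seeds(ring, "G0003", 3, rng_seed = 43)))

  # exactly one candidate in the seed's bin: the draw is forced
  edge <- tiny_graph("A", "B")
  expect_identical(sample_null_seeds(edge, "A", 1, rng_seed = 7)[[1]], "B")

  # hub with no degree peer: error names the seed and degree
  star <- make_graph("star", 6)
  expect_error(sample_null_seeds(star, "G0001", 1), "G0001.*degree 5")
  expect_error(sample_null_seeds(ring, "G0003", 0), "at least 1")
})

test_that("null seed sets are drawn without replacement within one set", {
  ring <- make_graph("ring", 10)
  sets <- sample_null_seeds(ring, c("G0001", "G0002", "G0003"), 50, rng_seed = 1)
  for (s in sets) expect_equal(anyDuplicated(s), 0)
})

test_that("empirical p-values follow the add-one permutation formula", {
  obs <- c(A = 0.9)
  expect_equal(unname(empirical_pvalues(obs, matrix(runif(99, 0, 0.5), 1))), 0.01)
  expect_equal(unname(empirical_pvalues(c(A = 0), matrix(runif(50, 0.1, 1), 1))), 1)

  # tie handling: 5 of 10 nulls equal the observed value
  nulls <- matrix(c(rep(0.7, 5), rep(0.1, 5)), nrow = 1)
  expect_equal(unname(empirical_pvalues(c(A = 0.7), nulls)), 6 / 11)

  expect_error(empirical_pvalues(c(A = 1, B = 2), matrix(0, 1, 5)), "one row per")
})

test_that("p-value adjustment matches independent BH and Holm oracles", {
  expect_equal(adjust_pvalues(c(x = 0.03), "bonferroni"), c(x = 0.03))
  expect_equal(unname(adjust_pvalues(c(0.01, 0.02, 0.03), "bonferroni")),
               c(0.03, 0.06, 0.09))

  p <- c(a = 0.01, b = 0.02, c = 0.04, d = 0.04)
  expect_equal(adjust_pvalues(p, "BH"), bh_oracle(p))

  for (s in 1:10) {
    pr <- withr::with_seed(s, runif(20)^2)
    names(pr) <- paste0("n", 1:20)
    expect_equal(adjust_pvalues(pr, "BH"), bh_oracle(pr), tolerance = 1e-12)
    expect_equal(adjust_pvalues(pr, "holm"), holm_oracle(pr), tolerance = 1e-12)
    expect_true(all(adjust_pvalues(pr, "BH") >= pr - 1e-15))
  }
  expect_error(adjust_pvalues(c(0.1), "fdr_by"))
  expect_error(adjust_pvalues(c(-0.1), "BH"), "\\[0, 1\\]")
})

test_that("compute_crosstalk retains the hub seed with the top affinity", {
  g <- double_star(5)
  ct <- compute_crosstalk(g, "H1", rwr_params(eps = 1e-12),
                          n_bootstrap = 50, rng_seed = 3,
                          significance_level = 0.5)
  expect_true("H1" %in% ct$result$node)
  row1 <- ct$result[1, ]
  expect_equal(row1$node, "H1")
  expect_true(row1$seed)
  expect_equal(max(ct$result$affinity_score), row1$affinity_score)
  # result is sorted: seeds first, affinity descending, id ascending
  rest <- ct$result[-1, ]
  expect_true(all(diff(rest$affinity_score) <= 1e-15 |
                    diff(match(rest$node, sort(rest$node))) > 0))
  # retained subgraph is the induced subgraph on the retained rows
  expect_true(identical_graphs(ct$subgraph, keep_nodes(g, ct$result$node)))
})

test_that("nodes disconnected from the seeds are never retained", {
  g <- make_graph("two_cliques", 10)
  clique2 <- sprintf("G%04d", 6:10)
  ct <- compute_crosstalk(g, "G0001", rwr_params(eps = 1e-12),
                          n_bootstrap = 30, rng_seed = 5,
                          significance_level = 0.9)
  expect_length(intersect(ct$result$node, clique2), 0)
  # their observed affinity is exactly zero, so p = 1 regardless of the null
  av <- random_walk(g, "G0001", rwr_params(eps = 1e-12))
  expect_true(all(av$scores[clique2] == 0))
})

test_that("crosstalk results are reproducible and honour n_bootstrap >= 1", {
  g <- double_star(4)
  a <- compute_crosstalk(g, "H1", n_bootstrap = 20, rng_seed = 9,
                         significance_level = 0.5)
  b <- compute_crosstalk(g, "H1", n_bootstrap = 20, rng_seed = 9,
                         significance_level = 0.5)
  expect_identical(a$result, b$result)
  expect_error(compute_crosstalk(g, "H1", n_bootstrap = 0), "at least 1")
})

test_that("an empty retained set warns and returns an empty table", {
  ring <- make_graph("ring", 12)
  expect_warning(
    ct <- compute_crosstalk(ring, "G0001", n_bootstrap = 19, rng_seed = 2,
                            significance_level = 1e-6),
    "no node")
  expect_equal(nrow(ct$result), 0)
  expect_equal(igraph::vcount(ct$subgraph), 0)
})

test_that("crosstalk tables and subgraphs serialise deterministically", {
  g <- double_star(4)
  ct <- compute_crosstalk(g, "H1", n_bootstrap = 20, rng_seed = 9,
                          significance_level = 0.5)
  f1 <- tempfile(); f2 <- tempfile()
  write_crosstalk(ct, f1)
  write_crosstalk(ct, f2)
  expect_identical(readLines(f1), readLines(f2))
  d <- utils::read.delim(f1)
  expect_identical(names(d),
                   c("node", "seed", "affinity_score", "p_value", "adj_p_value"))
  expect_true(all(d$adj_p_value >= d$p_value - 1e-12))
  expect_true(all(d$p_value > 0)) # add-one correction: never exactly zero

  gml <- tempfile(fileext = ".graphml")
  write_graphml(ct$subgraph, gml)
  expect_true(any(grepl("graphml", readLines(gml, n = 3))))
})
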