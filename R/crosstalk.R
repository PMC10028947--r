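# Seed-anchored subnetwork identification: observed RWR affinities compared
# per node against a bootstrapped null built from degree-matched random seed
# sets, with empirical p-values and multiplicity adjustment.

# Logarithmic degree bin: a seed of degree d matches candidates with
# floor(log2(d)) equal, e.g. degree 100 matches degrees 64..127. Exact-degree
# matching starves bins in sparse graphs.
degree_bin <- function(deg) floor(log2(pmax(deg, 1L)))

#' Degree-matched null seed sets
#'
#' Draws `n_bootstrap` random seed sets whose degree distribution resembles
#' the observed seeds': each observed seed is replaced by a non-seed node
#' drawn uniformly from the same logarithmic degree bin, without replacement
#' within one set. Replicate b derives its RNG stream from `rng_seed + b`, so
#' results are reproducible and independent of execution order.
#'
#' @param g An igraph object.
#' @param seeds Character vector of observed seed identifiers.
#' @param n_bootstrap Number of null seed sets to draw (>= 1).
#' @param rng_seed Integer seed for reproducibility.
#' @return A list of `n_bootstrap` character vectors, each of
#'   `length(seeds)`.
#' @export
sample_null_seeds <- function(g, seeds, n_bootstrap, rng_seed = 1L) {
  seeds <- unique(as.character(seeds))
  n_bootstrap <- as.integer(n_bootstrap)
  if (is.na(n_bootstrap) || n_bootstrap < 1L) {
    stop("n_bootstrap must be at least 1", call. = FALSE)
  }
  nodes <- igraph::V(g)$name
  unknown <- setdiff(seeds, nodes)
  if (length(unknown) > 0L) {
    stop("unknown seed id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  deg <- as.integer(igraph::degree(g))
  names(deg) <- nodes
  bins <- degree_bin(deg)
  non_seed <- setdiff(nodes, seeds)
  # candidate pools per observed seed, in deterministic (sorted) seed order
  seeds <- sort(seeds)
  pools <- lapply(seeds, function(s) {
    cand <- sort(non_seed[bins[non_seed] == bins[[s]]])
    if (length(cand) == 0L) {
      stop(sprintf("no degree-matched candidate for seed '%s' (degree %d)",
                   s, deg[[s]]), call. = FALSE)
    }
    cand
  })
  lapply(seq_len(n_bootstrap), function(b) {
    withr::with_seed(rng_seed + b, {
      drawn <- character(0L)
      for (k in seq_along(seeds)) {
        cand <- setdiff(pools[[k]], drawn)
        if (length(cand) == 0L) {
          stop(sprintf(
            "degree bin exhausted for seed '%s' (degree %d): cannot draw without replacement",
            seeds[[k]], deg[[seeds[[k]]]]), call. = FALSE)
        }
        drawn <- c(drawn, cand[[sample.int(length(cand), 1L)]])
      }
      drawn
    })
  })
}

#' Empirical permutation p-values with add-one correction
#'
#' For each node, p = (1 + number of null draws >= observed) / (1 + B). Ties
#' count as exceeding; the add-one correction keeps p strictly positive for
#' finite B.
#'
#' @param observed Named numeric vector of observed scores.
#' @param null_scores Numeric matrix with one row per node (rownames matching
#'   `names(observed)`) and one column per bootstrap draw.
#' @return Named numeric vector of p-values in (0, 1].
#' @export
empirical_pvalues <- function(observed, null_scores) {
  null_scores <- as.matrix(null_scores)
  if (nrow(null_scores) != length(observed)) {
    stop("null_scores must have one row per observed node", call. = FALSE)
  }
  if (!is.null(rownames(null_scores))) {
    if (!setequal(rownames(null_scores), names(observed))) {
      stop("rownames of null_scores do not match names of observed", call. = FALSE)
    }
    null_scores <- null_scores[names(observed), , drop = FALSE]
  }
  B <- ncol(null_scores)
  p <- (1 + rowSums(null_scores >= observed)) / (1 + B)
  names(p) <- names(observed)
  p
}

#' Multiple-testing adjustment
#'
#' Thin, validated wrapper over [stats::p.adjust()] for the three supported
#' methods (Benjamini-Hochberg step-up, Holm step-down, Bonferroni scaling).
#'
#' @param p Named numeric vector of p-values in \[0, 1\].
#' @param method One of `"BH"`, `"bonferroni"`, `"holm"`.
#' @return Named numeric vector of adjusted p-values, capped at 1.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni", "holm")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = method)
}

#' Identify a seed-specific subnetwork by network propagation
#'
#' The full pipeline: run the observed random walk with restarts from the
#' user seeds; run `n_bootstrap` walks from degree-matched random seed sets
#' ([sample_null_seeds()]) over the same transition matrix; compare each
#' node's observed affinity with its own null distribution
#' ([empirical_pvalues()]); adjust for multiplicity; and retain nodes with
#' adjusted p below `significance_level`.
#'
#' @inheritParams random_walk
#' @param g An igraph object.
#' @param n_bootstrap Number of null walks. Default 1000.
#' @param rng_seed Integer seed controlling the null seed draws.
#' @param significance_level Retain nodes with adjusted p strictly below this.
#' @param p_adjust Adjustment method, see [adjust_pvalues()].
#' @return A list of class `crosstalk_result` with elements `result` (a
#'   data.frame with columns `node`, `seed`, `affinity_score`, `p_value`,
#'   `adj_p_value`, seeds first then affinity descending, node id as
#'   tie-break) and `subgraph` (the induced subgraph on the retained nodes).
#'   Reported p-values carry the add-one correction and are never exactly 0:
#'   a node beating every null draw reports p = 1/(B + 1).
#' @export
compute_crosstalk <- function(g, seeds, params = rwr_params(),
                              n_bootstrap = 1000L, rng_seed = 1L,
                              significance_level = 0.05,
                              p_adjust = c("BH", "bonferroni", "holm")) {
  p_adjust <- match.arg(p_adjust)
  if (significance_level <= 0 || significance_level > 1) {
    stop("significance_level must be in (0, 1]", call. = FALSE)
  }
  seeds <- unique(as.character(seeds))
  tm <- to_transition_matrix(g)
  observed <- random_walk(tm, seeds, params)

  null_sets <- sample_null_seeds(g, seeds, n_bootstrap, rng_seed)
  null_scores <- null_affinities(tm, null_sets, params)

  p <- empirical_pvalues(observed$scores, null_scores)
  adj <- adjust_pvalues(p, p_adjust)

  retained <- names(adj)[adj < significance_level]
  if (length(retained) == 0L) {
    warning("no node reached the significance level; returning an empty result",
            call. = FALSE)
  }
  res <- data.frame(node = retained,
                    seed = retained %in% seeds,
                    affinity_score = unname(observed$scores[retained]),
                    p_value = unname(p[retained]),
                    adj_p_value = unname(adj[retained]),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$seed, -res$affinity_score, res$node), , drop = FALSE]
  rownames(res) <- NULL
  sub <- igraph::induced_subgraph(g, retained)
  structure(list(result = res, subgraph = sub, seeds = seeds,
                 n_bootstrap = as.integer(n_bootstrap)),
            class = "crosstalk_result")
}

# Null affinity matrix: one column per bootstrap seed set, iterated in
# batches so the whole null costs a few sparse matrix products.
null_affinities <- function(tm, null_sets, params, batch_size = 250L) {
  n <- length(tm$nodes)
  B <- length(null_sets)
  out <- matrix(0, nrow = n, ncol = B, dimnames = list(tm$nodes, NULL))
  for (start in seq(1L, B, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, B)
    R <- vapply(null_sets[idx], function(s) restart_vector(tm, s), numeric(n))
    out[, idx] <- rwr_iterate(tm$matrix, R, params$gamma, params$eps,
                              params$tmax)$p
  }
  out
}

#' @export
print.crosstalk_result <- function(x, ...) {
  cat(sprintf("Crosstalk subnetwork: %d node(s) retained (%d seed(s), B = %d)\n",
              nrow(x$result), length(x$seeds), x$n_bootstrap))
  print(utils::head(x$result, 10L))
  invisible(x)
}

#' Write a crosstalk result table to TSV
#'
#' Columns: `node`, `seed`, `affinity_score`, `p_value`, `adj_p_value`.
#'
#' @param x A `crosstalk_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_crosstalk <- function(x, path) {
  stopifnot(inherits(x, "crosstalk_result"))
  utils::write.table(format(x$result, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a graph as an edge-list TSV
#'
#' Header `node_a`, `node_b` and, when present, `confidence`; endpoints
#' ordered within each row and rows sorted so output is deterministic.
#'
#' @param g An igraph object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edgelist_tsv <- function(g, path) {
  utils::write.table(graph_edge_table(g), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a graph from an edge-list TSV
#'
#' Inverse of [write_edgelist_tsv()].
#'
#' @param path File path.
#' @return An igraph object.
#' @export
read_edgelist_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("edge-list TSV needs at least two columns", call. = FALSE)
  build_graph(d)
}

#' Write a graph in GraphML format
#'
#' @param g An igraph object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
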