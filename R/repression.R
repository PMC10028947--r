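# In-silico repression: score a node by the change in total network potential
# when it is deleted. Six steps per target i: score every node (s_v); total
# S = sum s_v; remove i; re-score only the affected nodes (i's neighbours —
# deleting i changes no other neighbourhood sum); S_i = sum over v != i of
# the new scores; Delta S_i = S - S_i. The removed node's own score sits on
# the matrix diagonal so the column-sum identity colSum(i) == Delta S_i is
# literal.

#' In-silico repression of target nodes
#'
#' For each target, computes the per-node change in network potential caused
#' by deleting that target, exploiting the fact that only the target itself
#' and its direct neighbours are affected: a neighbour v of i loses C_i from
#' its neighbourhood sum, every other node is untouched. Entry (j, i) of the
#' returned sparse matrix is `s_j - s_j_after_removal_of_i` for neighbours j,
#' and `s_i` itself on the diagonal; each column sums exactly to
#' `Delta S_i = S - S_i`, the global repression score of target i.
#'
#' @param g An igraph object whose nodes all carry positive weights in
#'   `weights`.
#' @param weights Named numeric vector of positive node weights (expression).
#' @param targets Character vector of nodes to repress; defaults to all
#'   nodes.
#' @param state_function State function tag; only `"network_potential"` is
#'   currently available (the interface is a placeholder for additional
#'   per-node state functions).
#' @return An object of class `repression_matrix`: list with `matrix` (sparse
#'   nodes x targets [Matrix::dgCMatrix-class]), `delta_S` (named column
#'   sums), `nodes`, `targets`, `state_function`.
#' @examples
#' g <- build_graph(data.frame(a = "A", b = "B"))
#' m <- node_repression(g, c(A = 1, B = 1), "B")
#' m$delta_S # 2 * log(1/2)
#' @export
node_repression <- function(g, weights, targets = igraph::V(g)$name,
                            state_function = "network_potential") {
  if (!identical(state_function, "network_potential")) {
    stop("only the 'network_potential' state function is available",
         call. = FALSE)
  }
  targets <- unique(as.character(targets))
  if (length(targets) == 0L) stop("no targets supplied", call. = FALSE)
  nodes <- sort(igraph::V(g)$name)
  unknown <- setdiff(targets, nodes)
  if (length(unknown) > 0L) {
    stop("target(s) not in the graph: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  targets <- sort(targets)
  s <- network_potential(g, weights)          # s_v for all v (step 1)
  C <- weights[names(s)]
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  A <- methods::as(A, "dMatrix")[names(s), names(s), drop = FALSE]
  nb_sum <- as.numeric(A %*% C)
  names(nb_sum) <- names(s)

  ii <- integer(0L); jj <- integer(0L); xx <- numeric(0L)
  adj <- igraph::as_adj_list(g)
  vnames <- igraph::V(g)$name
  for (k in seq_along(targets)) {
    tgt <- targets[[k]]
    nb <- vnames[adj[[match(tgt, vnames)]]]
    if (length(nb) > 0L) {
      # neighbour v loses C_tgt from its neighbourhood sum (step 4)
      new_arg <- C[nb] / (C[nb] + nb_sum[nb] - C[[tgt]])
      s_after <- C[nb] * log(new_arg)
      ii <- c(ii, match(nb, nodes))
      jj <- c(jj, rep.int(k, length(nb)))
      xx <- c(xx, unname(s[nb] - s_after))
    }
    # the removed node's own score: present in S, absent from S_i
    ii <- c(ii, match(tgt, nodes))
    jj <- c(jj, k)
    xx <- c(xx, unname(s[[tgt]]))
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(nodes), length(targets)),
                            dimnames = list(nodes, targets))
  delta_S <- Matrix::colSums(m)
  structure(list(matrix = m, delta_S = delta_S, nodes = nodes,
                 targets = targets, state_function = state_function),
            class = "repression_matrix")
}

#' @export
print.repression_matrix <- function(x, ...) {
  cat(sprintf("Repression matrix (%s): %d nodes x %d targets\n",
              x$state_function, length(x$nodes), length(x$targets)))
  print(utils::head(rank_targets(x), 10L))
  invisible(x)
}

#' Rank repression targets by global impact
#'
#' Orders targets by the magnitude of their global repression score
#' `Delta S` (network potential is negative, so removals typically drive
#' `Delta S` negative; magnitude ranking surfaces the most critical nodes
#' regardless of sign). The signed value is reported so users can re-rank.
#'
#' @param m A `repression_matrix` from [node_repression()].
#' @return A data.frame with columns `node` and `delta_S`, sorted by
#'   `abs(delta_S)` descending, node id ascending as tie-break.
#' @export
rank_targets <- function(m) {
  stopifnot(inherits(m, "repression_matrix"))
  if (length(m$targets) == 0L) stop("empty repression matrix", call. = FALSE)
  d <- data.frame(node = m$targets, delta_S = unname(m$delta_S),
                  stringsAsFactors = FALSE)
  d <- d[order(-abs(d$delta_S), d$node), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Degree-preserving graph randomisation
#'
#' Rewires a graph by repeated double-edge swaps that reject self-loops and
#' multi-edges, leaving every node's degree unchanged (igraph's
#' `keeping_degseq` rewiring). Performs `ceiling(swap_multiplier * |E|)`
#' swap attempts. Edge attributes are not carried over; vertex attributes
#' are. Graphs with fewer than two edges admit no swap and are returned
#' unchanged with a warning.
#'
#' @param g An igraph object.
#' @param swap_multiplier Swap attempts as a multiple of the edge count.
#'   Default 10.
#' @param rng_seed Integer seed; the result is reproducible.
#' @return A rewired igraph object with the identical degree sequence.
#' @export
rewire_preserving_degrees <- function(g, swap_multiplier = 10, rng_seed = 1L) {
  if (igraph::ecount(g) < 2L) {
    warning("graph has fewer than two edges; no degree-preserving swap exists",
            call. = FALSE)
    return(g)
  }
  niter <- as.integer(ceiling(swap_multiplier * igraph::ecount(g)))
  withr::with_seed(rng_seed,
    igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = niter)))
}

#' Rewired-graph null for repression scores
#'
#' Builds an empirical null for `Delta S` by recomputing the repression score
#' of every target on `n_rewires` degree-preserving randomisations of the
#' graph (weights stay attached to their node identities; only topology is
#' randomised). Per target, p = (1 + number of rewires with
#' `|Delta S_null| >= |Delta S_observed|`) / (1 + n_rewires).
#'
#' @inheritParams node_repression
#' @param n_rewires Number of rewired graphs (>= 1).
#' @param swap_multiplier Passed to [rewire_preserving_degrees()].
#' @param rng_seed Integer seed; rewire b uses stream `rng_seed + b`.
#' @return A data.frame with columns `node`, `delta_S`, `p_value`, ordered as
#'   [rank_targets()].
#' @export
compute_null_dnp <- function(g, weights, targets = igraph::V(g)$name,
                             n_rewires = 100L, swap_multiplier = 10,
                             rng_seed = 1L) {
  n_rewires <- as.integer(n_rewires)
  if (is.na(n_rewires) || n_rewires < 1L) {
    stop("n_rewires must be at least 1", call. = FALSE)
  }
  obs <- node_repression(g, weights, targets)
  ranked <- rank_targets(obs)
  null_mat <- matrix(NA_real_, nrow = length(obs$targets), ncol = n_rewires,
                     dimnames = list(obs$targets, NULL))
  for (b in seq_len(n_rewires)) {
    gb <- rewire_preserving_degrees(g, swap_multiplier, rng_seed + b)
    rb <- node_repression(gb, weights, obs$targets)
    null_mat[, b] <- rb$delta_S[obs$targets]
  }
  exceed <- rowSums(abs(null_mat) >= abs(obs$delta_S[rownames(null_mat)]))
  p <- (1 + exceed) / (1 + n_rewires)
  ranked$p_value <- unname(p[ranked$node])
  ranked
}

#' Write a repression matrix as sparse triplets plus a ranked summary
#'
#' Writes `<stem>_triplets.tsv` (`row_node`, `col_node`, `delta`) and
#' `<stem>_summary.tsv` (`node`, `delta_S`).
#'
#' @param m A `repression_matrix`.
#' @param stem Output path stem.
#' @return The two paths, invisibly.
#' @export
write_repression <- function(m, stem) {
  stopifnot(inherits(m, "repression_matrix"))
  tr <- Matrix::summary(m$matrix)
  d <- data.frame(row_node = m$nodes[tr$i], col_node = m$targets[tr$j],
                  delta = format(tr$x, digits = 15, scientific = FALSE,
                                 trim = TRUE),
                  stringsAsFactors = FALSE)
  d <- d[order(d$col_node, d$row_node), , drop = FALSE]
  p_trip <- paste0(stem, "_triplets.tsv")
  p_sum <- paste0(stem, "_summary.tsv")
  utils::write.table(d, p_trip, sep = "\t", quote = FALSE, row.names = FALSE)
  s <- rank_targets(m)
  s$delta_S <- format(s$delta_S, digits = 15, scientific = FALSE, trim = TRUE)
  utils::write.table(s, p_sum, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p_trip, p_sum))
}
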