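# Random walk with restarts over a sparse column-stochastic matrix.
#
# Update rule: p <- (1 - gamma) * W %*% p + gamma * r, with p0 = r and r the
# uniform distribution over the seed set. gamma is the restart probability;
# the stationary p is the affinity of every node for the seeds.

#' Random-walk parameters
#'
#' Bundles and validates the three tunables of the walk: `gamma`, the restart
#' probability in (0, 1]; `eps`, the L1 convergence threshold on the change in
#' p per iteration; and `tmax`, the iteration cap.
#'
#' @param gamma Restart probability. Default 0.6.
#' @param eps Stop when the L1 change in p in one iteration falls below this.
#' @param tmax Maximum number of iterations.
#' @return A list of class `rwr_params`.
#' @export
rwr_params <- function(gamma = 0.6, eps = 1e-10, tmax = 200L) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0 || gamma > 1) {
    stop("gamma must be a single number in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0) {
    stop("eps must be a single positive number", call. = FALSE)
  }
  tmax <- as.integer(tmax)
  if (is.na(tmax) || tmax < 1L) stop("tmax must be a positive integer", call. = FALSE)
  structure(list(gamma = gamma, eps = eps, tmax = tmax), class = "rwr_params")
}

# Coerce an igraph or transition_matrix argument to a transition_matrix.
as_transition <- function(w) {
  if (inherits(w, "transition_matrix")) return(w)
  if (igraph::is_igraph(w)) return(to_transition_matrix(w))
  stop("expected an igraph object or a transition_matrix", call. = FALSE)
}

# Batched power iteration: R is a dense n x k matrix of restart vectors, one
# walk per column. Returns list(p = n x k matrix, iterations, converged).
# Iterating all columns together keeps the bootstrap null to a handful of
# sparse matrix products instead of thousands.
rwr_iterate <- function(W, R, gamma, eps, tmax) {
  P <- R
  iterations <- 0L
  converged <- FALSE
  for (t in seq_len(tmax)) {
    P_new <- (1 - gamma) * as.matrix(W %*% P) + gamma * R
    delta <- max(colSums(abs(P_new - P)))
    P <- P_new
    iterations <- t
    if (delta < eps) {
      converged <- TRUE
      break
    }
  }
  list(p = P, iterations = iterations, converged = converged)
}

# Validate a seed set against a transition matrix; returns the restart vector.
restart_vector <- function(tm, seeds) {
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L) stop("at least one seed is required", call. = FALSE)
  unknown <- setdiff(seeds, tm$nodes)
  if (length(unknown) > 0L) {
    stop("unknown seed id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  col_mass <- Matrix::colSums(tm$matrix)
  if (all(col_mass == 0)) {
    stop("the transition matrix is all zero (no edges)", call. = FALSE)
  }
  isolated <- seeds[col_mass[match(seeds, tm$nodes)] == 0]
  if (length(isolated) > 0L) {
    stop("seed(s) are isolated nodes: ", paste(isolated, collapse = ", "),
         call. = FALSE)
  }
  r <- numeric(length(tm$nodes))
  r[match(seeds, tm$nodes)] <- 1 / length(seeds)
  r
}

#' Random walk with restarts
#'
#' Propagates signal from a seed set across the network. Starting from the
#' restart distribution (uniform over the seeds), the walk repeatedly either
#' steps to a uniformly chosen neighbour (probability `1 - gamma`) or restarts
#' at the seeds (probability `gamma`); the fixed point is the per-node
#' affinity score. Iteration stops when the L1 change in one step drops below
#' `eps`, or after `tmax` iterations.
#'
#' @param w An igraph object or a `transition_matrix` from
#'   [to_transition_matrix()].
#' @param seeds Character vector of seed node identifiers. All must exist in
#'   the graph and none may be isolated.
#' @param params An [rwr_params()] object.
#' @return An object of class `affinity_vector`: a list with `scores` (named
#'   numeric over all nodes, summing to 1), `seeds`, `converged` and
#'   `iterations`.
#' @examples
#' g <- build_graph(data.frame(a = "A", b = "B"))
#' av <- random_walk(g, "A", rwr_params(gamma = 0.5, eps = 1e-14))
#' av$scores # A = 2/3, B = 1/3
#' @export
random_walk <- function(w, seeds, params = rwr_params()) {
  tm <- as_transition(w)
  if (!inherits(params, "rwr_params")) params <- do.call(rwr_params, as.list(params))
  r <- restart_vector(tm, seeds)
  res <- rwr_iterate(tm$matrix, matrix(r, ncol = 1L),
                     params$gamma, params$eps, params$tmax)
  scores <- drop(res$p)
  names(scores) <- tm$nodes
  structure(list(scores = scores,
                 seeds = unique(as.character(seeds)),
                 converged = res$converged,
                 iterations = res$iterations),
            class = "affinity_vector")
}

#' @export
print.affinity_vector <- function(x, ...) {
  cat(sprintf("Affinity vector over %d nodes (%d seeds); %s in %d iterations\n",
              length(x$scores), length(x$seeds),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(utils::head(sort(x$scores, decreasing = TRUE), 10L))
  invisible(x)
}

#' Exact stationary affinity by dense linear solve
#'
#' Solves p = gamma * (I - (1 - gamma) W)^{-1} r directly. Intended as a
#' small-graph oracle for the iterative walk; guarded to at most 2000 nodes.
#'
#' @inheritParams random_walk
#' @param gamma Restart probability in (0, 1].
#' @return An `affinity_vector` with `converged = TRUE` and `iterations = 0`.
#' @export
solve_rwr_exact <- function(w, seeds, gamma = 0.6) {
  tm <- as_transition(w)
  n <- length(tm$nodes)
  if (n > 2000L) {
    stop("dense solve guarded to graphs of at most 2000 nodes", call. = FALSE)
  }
  if (gamma <= 0 || gamma > 1) stop("gamma must be in (0, 1]", call. = FALSE)
  r <- restart_vector(tm, seeds)
  A <- diag(n) - (1 - gamma) * as.matrix(tm$matrix)
  p <- gamma * solve(A, r)
  names(p) <- tm$nodes
  structure(list(scores = p, seeds = unique(as.character(seeds)),
                 converged = TRUE, iterations = 0L),
            class = "affinity_vector")
}
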