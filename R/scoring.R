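# Node scoring and score-based graph filtration.
#
# Network potential (Gibbs free energy) of node i with expression weight C_i
# and neighbour weights C_j:
#
#     G_i = C_i * ln( C_i / (C_i + sum_j C_j) )
#
# The log argument lies in (0, 1], so G_i <= 0; an isolated node scores
# exactly 0. The total network state S = sum_i G_i is the quantity perturbed
# by in-silico repression.

#' Network potential (Gibbs free energy) of every node
#'
#' Scores each node i as `C_i * log(C_i / (C_i + sum of neighbour C_j))`,
#' where C are strictly positive per-node expression weights. Every node of
#' the graph must have a finite positive weight; drop unweighted nodes first
#' (see [gfilter_by_value()]).
#'
#' @param g An igraph object.
#' @param weights Named numeric vector of positive node weights covering all
#'   nodes of `g` (extra names are ignored).
#' @return Named numeric vector of scores, all `<= 0`, with attribute
#'   `method = "network_potential"`.
#' @examples
#' g <- build_graph(data.frame(a = "A", b = "B"))
#' network_potential(g, c(A = 1, B = 1)) # both log(1/2)
#' @export
network_potential <- function(g, weights) {
  nodes <- igraph::V(g)$name
  C <- weights[nodes]
  bad <- nodes[is.na(C) | !is.finite(C) | C <= 0]
  if (length(bad) > 0L) {
    stop("missing or non-positive weight for node(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  names(C) <- nodes
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  A <- methods::as(A, "dMatrix")[nodes, nodes, drop = FALSE]
  nb_sum <- as.numeric(A %*% C)
  scores <- C * log(C / (C + nb_sum))
  names(scores) <- nodes
  attr(scores, "method") <- "network_potential"
  scores
}

#' Betweenness centrality
#'
#' Unnormalised vertex betweenness over unweighted shortest paths: the sum
#' over unordered node pairs (s, t) of the fraction of shortest s-t paths
#' passing through v. Delegates to [igraph::betweenness()].
#'
#' @param g An igraph object.
#' @return Named numeric vector with attribute `method = "betweenness"`.
#' @export
betweenness_score <- function(g) {
  scores <- igraph::betweenness(g, directed = FALSE, weights = NA)
  attr(scores, "method") <- "betweenness"
  scores
}

#' Degree score
#'
#' Number of neighbours of each node.
#'
#' @param g An igraph object.
#' @return Named numeric vector with attribute `method = "degree"`.
#' @export
degree_score <- function(g) {
  scores <- igraph::degree(g)
  attr(scores, "method") <- "degree"
  scores
}

#' Filter a graph to its top-scoring nodes
#'
#' Keeps the `n` best nodes under a per-node score and returns the induced
#' subgraph. Ties are broken by node identifier ascending; when `n` is at
#' least the node count the graph is returned unchanged.
#'
#' @param g An igraph object.
#' @param scores Named numeric vector covering every node of `g`.
#' @param n Number of nodes to keep (>= 1).
#' @param descending If `TRUE` (default) keep the largest scores, else the
#'   smallest.
#' @return The induced subgraph on the selected nodes.
#' @export
gfilter <- function(g, scores, n, descending = TRUE) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer", call. = FALSE)
  nodes <- igraph::V(g)$name
  missing <- nodes[!nodes %in% names(scores)]
  if (length(missing) > 0L) {
    stop("scores missing for node(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (n >= length(nodes)) return(g)
  s <- unname(scores[nodes])
  ord <- order(if (descending) -s else s, nodes)
  keep_nodes(g, nodes[ord[seq_len(n)]])
}

#' Filter a graph by a user-supplied value vector (e.g. expression)
#'
#' Nodes absent from `values` are excluded from ranking and from the result;
#' the top (or bottom) `n` valued nodes are kept and each surviving node
#' carries its value as the `weight` vertex attribute, ready for
#' [network_potential()].
#'
#' @param g An igraph object.
#' @param values Named numeric vector (e.g. log-scale gene expression).
#' @param n Number of nodes to keep.
#' @param descending If `TRUE` (default) keep the largest values.
#' @return The induced subgraph with vertex attribute `weight`.
#' @export
gfilter_by_value <- function(g, values, n, descending = TRUE) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer", call. = FALSE)
  nodes <- igraph::V(g)$name
  scored <- nodes[nodes %in% names(values)]
  if (length(scored) == 0L) {
    stop("no node of the graph has a value; check identifier namespaces",
         call. = FALSE)
  }
  v <- unname(values[scored])
  ord <- order(if (descending) -v else v, scored)
  keep <- scored[ord[seq_len(min(n, length(scored)))]]
  sub <- keep_nodes(g, keep)
  igraph::V(sub)$weight <- unname(values[igraph::V(sub)$name])
  sub
}

#' Write a node score vector as a two-column TSV
#'
#' @param scores Named numeric vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  d <- data.frame(node = names(scores),
                  score = format(unname(scores), digits = 15,
                                 scientific = FALSE, trim = TRUE),
                  stringsAsFactors = FALSE)
  d <- d[order(d$node), , drop = FALSE]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
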