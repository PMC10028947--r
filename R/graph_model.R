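# Core graph representation and stochastic normalisation.
#
# Graphs are plain igraph objects: vertices named by protein/gene identifier,
# an optional `confidence` edge attribute (StringDB combined_score scale) and
# an optional `weight` vertex attribute holding the per-node expression weight
# C_i used by the network-potential score.

#' Build a simple undirected graph from edge records
#'
#' Constructs the canonical graph object used throughout the package from a
#' two- or three-column edge table. Self-loops are dropped, duplicate edges
#' (in either orientation) are collapsed, and when a confidence column is
#' present the maximum confidence among duplicates is kept.
#'
#' @param edges A data.frame (or matrix) whose first two columns are node
#'   identifiers and whose optional third column is a non-negative edge
#'   confidence.
#' @return An undirected, simple [igraph::graph] with vertex attribute `name`
#'   and, when supplied, edge attribute `confidence`.
#' @examples
#' g <- build_graph(data.frame(a = c("A", "B", "A"), b = c("B", "A", "A")))
#' igraph::ecount(g) # 1
#' @export
build_graph <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) {
    stop("no usable edges: the edge table is empty", call. = FALSE)
  }
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  conf <- if (ncol(edges) >= 3L) as.numeric(edges[[3L]]) else NULL
  keep <- !is.na(a) & !is.na(b) & a != b
  if (!any(keep)) {
    stop("no usable edges after dropping self-loops", call. = FALSE)
  }
  a <- a[keep]
  b <- b[keep]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  if (is.null(conf)) {
    d <- unique(data.frame(from = lo, to = hi, stringsAsFactors = FALSE))
    g <- igraph::graph_from_data_frame(d, directed = FALSE)
  } else {
    conf <- conf[keep]
    key <- paste(lo, hi, sep = "\r")
    cmax <- tapply(conf, key, max)
    first <- !duplicated(key)
    d <- data.frame(from = lo[first], to = hi[first],
                    confidence = as.numeric(cmax[key[first]]),
                    stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(d, directed = FALSE)
  }
  g
}

#' Column-stochastic transition matrix of a graph
#'
#' Converts a graph into the sparse transition matrix driving the random walk
#' with restarts: column j holds 1/deg(j) at the rows of j's neighbours, so
#' every non-isolated column sums to one. Isolated nodes yield an all-zero
#' column (they have no in-edges in an undirected graph, so no walk mass can
#' enter them). Rows and columns follow a fixed lexicographic node order for
#' determinism across runs. The walk is unweighted: edge confidence only
#' filters edges on ingest and never reweights transitions.
#'
#' @param g An igraph object from [build_graph()] or the parsers.
#' @return An object of class `transition_matrix`: a list with `matrix` (a
#'   sparse [Matrix::dgCMatrix-class]) and `nodes` (the row/column order).
#' @export
to_transition_matrix <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0L) {
    stop("cannot build a transition matrix from an empty graph", call. = FALSE)
  }
  nodes <- sort(igraph::V(g)$name)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  A <- A[nodes, nodes, drop = FALSE]
  A <- methods::as(A, "dMatrix")
  deg <- Matrix::colSums(A)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  W <- A %*% Matrix::Diagonal(x = inv)
  W <- methods::as(methods::as(W, "CsparseMatrix"), "generalMatrix")
  dimnames(W) <- list(nodes, nodes)
  structure(list(matrix = W, nodes = nodes), class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("Transition matrix: %d nodes, %d nonzero entries\n",
              length(x$nodes), Matrix::nnzero(x$matrix)))
  invisible(x)
}

#' Induced subgraph on a kept node set
#'
#' Restricts a graph to `keep` and every edge with both endpoints kept.
#' Identifiers absent from the graph are silently ignored with a warning
#' giving their count; vertex attributes (including expression weights) are
#' preserved.
#'
#' @param g An igraph object.
#' @param keep Character vector of node identifiers to retain.
#' @return The induced subgraph, an igraph object.
#' @export
keep_nodes <- function(g, keep) {
  keep <- unique(as.character(keep))
  present <- keep[keep %in% igraph::V(g)$name]
  n_missing <- length(keep) - length(present)
  if (length(present) == 0L) {
    stop("none of the requested nodes are present in the graph", call. = FALSE)
  }
  if (n_missing > 0L) {
    warning(sprintf("%d requested node(s) not present in the graph were ignored",
                    n_missing), call. = FALSE)
  }
  igraph::induced_subgraph(g, present)
}

# Edge table of a graph as a data.frame (node_a, node_b [, confidence]),
# endpoints ordered within each row and rows sorted, so two structurally
# identical graphs yield identical tables.
graph_edge_table <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  d <- data.frame(node_a = pmin(el[, 1L], el[, 2L]),
                  node_b = pmax(el[, 1L], el[, 2L]),
                  stringsAsFactors = FALSE)
  if ("confidence" %in% igraph::edge_attr_names(g)) {
    d$confidence <- igraph::E(g)$confidence
  }
  d[order(d$node_a, d$node_b), , drop = FALSE]
}

#' Test two graphs for structural identity
#'
#' Compares node sets, edge sets and (when both carry it) the `confidence`
#' edge attribute. Used by the round-trip guarantees of the file writers.
#'
#' @param g1,g2 igraph objects.
#' @return `TRUE` or `FALSE`.
#' @export
identical_graphs <- function(g1, g2) {
  if (!setequal(igraph::V(g1)$name, igraph::V(g2)$name)) return(FALSE)
  e1 <- graph_edge_table(g1)
  e2 <- graph_edge_table(g2)
  if (nrow(e1) != nrow(e2)) return(FALSE)
  both_conf <- "confidence" %in% names(e1) && "confidence" %in% names(e2)
  if (!both_conf) {
    e1$confidence <- NULL
    e2$confidence <- NULL
  }
  rownames(e1) <- rownames(e2) <- NULL
  isTRUE(all.equal(e1, e2, check.attributes = FALSE))
}
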