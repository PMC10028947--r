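#' Plot a crosstalk subnetwork
#'
#' Minimal convenience plot of the retained subnetwork: seeds drawn larger,
#' vertex size scaled by affinity, optionally restricted to the top fraction
#' of retained nodes by affinity (`prop_keep`).
#'
#' @param x A `crosstalk_result` from [compute_crosstalk()].
#' @param prop_keep Fraction in (0, 1] of retained nodes (by affinity,
#'   descending) to draw. Default 1.
#' @param ... Passed on to [igraph::plot.igraph()].
#' @return The plotted igraph object, invisibly.
#' @export
plot_crosstalk <- function(x, prop_keep = 1, ...) {
  stopifnot(inherits(x, "crosstalk_result"))
  if (prop_keep <= 0 || prop_keep > 1) {
    stop("prop_keep must be in (0, 1]", call. = FALSE)
  }
  res <- x$result[order(-x$result$affinity_score), , drop = FALSE]
  keep <- res$node[seq_len(max(1L, ceiling(prop_keep * nrow(res))))]
  g <- igraph::induced_subgraph(x$subgraph, keep)
  aff <- res$affinity_score[match(igraph::V(g)$name, res$node)]
  is_seed <- igraph::V(g)$name %in% x$seeds
  igraph::plot.igraph(
    g,
    vertex.size = 5 + 25 * aff / max(aff),
    vertex.color = ifelse(is_seed, "tomato", "steelblue"),
    vertex.label.cex = 0.7, ...)
  invisible(g)
}
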