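# Seeded synthetic graphs and expression vectors. Everything in the test
# suite and the worked examples runs on these, so no repository download is
# ever needed to exercise the full pipeline.

#' Generate a synthetic graph
#'
#' Deterministic (for a fixed `rng_seed`) simple undirected graphs in five
#' shapes: `erdos_renyi` (edge probability `param`), `barabasi_albert`
#' (preferential attachment, `param` edges per new node), `ring`, `star`
#' (node 1 is the hub) and `two_cliques` (two disjoint cliques of
#' `n_nodes / 2`). Node identifiers are zero-padded (`"G0001"`, ...).
#'
#' @param model One of `"erdos_renyi"`, `"barabasi_albert"`, `"ring"`,
#'   `"star"`, `"two_cliques"`.
#' @param n_nodes Number of nodes (>= 2; even and >= 4 for `two_cliques`).
#' @param param Model parameter: edge probability for `erdos_renyi`,
#'   attachment count for `barabasi_albert`; ignored otherwise.
#' @param rng_seed Integer seed.
#' @return An igraph object with named vertices.
#' @export
make_graph <- function(model = c("erdos_renyi", "barabasi_albert", "ring",
                                 "star", "two_cliques"),
                       n_nodes, param = 0.1, rng_seed = 1L) {
  model <- match.arg(model)
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 2L) stop("n_nodes must be >= 2", call. = FALSE)
  g <- switch(model,
    erdos_renyi = withr::with_seed(rng_seed,
      igraph::sample_gnp(n_nodes, p = param, directed = FALSE)),
    barabasi_albert = withr::with_seed(rng_seed,
      igraph::sample_pa(n_nodes, m = max(1L, as.integer(param)),
                        directed = FALSE)),
    ring = igraph::make_ring(n_nodes),
    star = igraph::make_star(n_nodes, mode = "undirected"),
    two_cliques = {
      if (n_nodes %% 2L != 0L || n_nodes < 4L) {
        stop("two_cliques needs an even n_nodes >= 4", call. = FALSE)
      }
      igraph::disjoint_union(igraph::make_full_graph(n_nodes %/% 2L),
                             igraph::make_full_graph(n_nodes %/% 2L))
    })
  igraph::V(g)$name <- sprintf("G%04d", seq_len(n_nodes))
  g
}

#' Generate a synthetic expression vector for a graph
#'
#' One strictly positive lognormal draw per node, emulating a named numeric
#' vector of (linear-scale) gene expression. Reproducible for a fixed seed.
#'
#' @param g A named igraph object.
#' @param meanlog,sdlog Lognormal parameters. Defaults 2 and 1.
#' @param rng_seed Integer seed.
#' @return Named numeric vector, all values `> 0`.
#' @export
make_expression <- function(g, meanlog = 2, sdlog = 1, rng_seed = 1L) {
  nodes <- igraph::V(g)$name
  vals <- withr::with_seed(rng_seed,
                           stats::rlnorm(length(nodes), meanlog, sdlog))
  names(vals) <- nodes
  vals
}

#' Write fixture files in a supported dialect
#'
#' Emits a graph (and/or expression vector) as a small plain-text file in the
#' exact dialect the parsers consume, guaranteeing a parse round trip for
#' graphs without isolated vertices (edge-list dialects only carry
#' interacting nodes, so an isolated vertex is unrepresentable and dropped):
#' `stringdb` (both edge orientations, species-prefixed identifiers, the
#' edge's `confidence` attribute or 999 when absent), `biogrid` (official
#' symbol columns) or `expression` (identifier/value TSV).
#'
#' @param g An igraph object (ignored for `dialect = "expression"`).
#' @param e Named numeric expression vector (only for
#'   `dialect = "expression"`).
#' @param dialect `"stringdb"`, `"biogrid"` or `"expression"`.
#' @param dir Output directory (created if needed).
#' @param species_code Prefix for StringDB identifiers. Default `"9606"`.
#' @return The written file path, invisibly.
#' @export
write_fixture_files <- function(g = NULL, e = NULL,
                                dialect = c("stringdb", "biogrid", "expression"),
                                dir = tempdir(), species_code = "9606") {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- switch(dialect,
    stringdb = {
      el <- graph_edge_table(g)
      conf <- if ("confidence" %in% names(el)) el$confidence else
        rep.int(999L, nrow(el))
      d <- data.frame(
        protein1 = paste0(species_code, ".", c(el$node_a, el$node_b)),
        protein2 = paste0(species_code, ".", c(el$node_b, el$node_a)),
        combined_score = c(conf, conf))
      f <- file.path(dir, "protein_links.txt")
      utils::write.table(d, f, sep = " ", quote = FALSE, row.names = FALSE)
      f
    },
    biogrid = {
      el <- graph_edge_table(g)
      d <- data.frame(el$node_a, el$node_b, "physical",
                      stringsAsFactors = FALSE)
      names(d) <- c("Official Symbol Interactor A",
                    "Official Symbol Interactor B",
                    "Experimental System Type")
      f <- file.path(dir, "biogrid_interactions.txt")
      utils::write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
      f
    },
    expression = {
      stopifnot(!is.null(e))
      d <- data.frame(identifier = names(e),
                      value = format(unname(e), digits = 15,
                                     scientific = FALSE, trim = TRUE))
      f <- file.path(dir, "expression.tsv")
      utils::write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
      f
    })
  invisible(path)
}
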