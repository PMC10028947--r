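# Parsing, filtering and caching of PPI edge lists.
#
# Two repository dialects are supported: StringDB protein.links (whitespace-
# delimited, header "protein1 protein2 combined_score", identifiers prefixed
# with the species taxonomy code) and BioGRID tab-delimited interaction
# tables (official gene symbol columns). Both reduce to the simple undirected
# graph of build_graph().

#' Parse a StringDB protein-links file
#'
#' Reads a whitespace-delimited protein.links table, strips the species
#' prefix (e.g. `"9606."`) from identifiers, keeps edges with
#' `combined_score >= min_confidence` (StringDB's 0-1000 scale) and returns
#' the deduplicated undirected graph with a `confidence` edge attribute.
#'
#' @param path Path to the file (plain or gzipped).
#' @param min_confidence Minimum combined_score, integer in \[0, 1000\].
#'   Default 400, the conventional medium-confidence cutoff.
#' @param species_code Taxonomy code prefix to strip. Default `"9606"`
#'   (human).
#' @return An igraph object.
#' @export
parse_stringdb_links <- function(path, min_confidence = 400L,
                                 species_code = "9606") {
  if (min_confidence < 0 || min_confidence > 1000) {
    stop("min_confidence must lie in [0, 1000]", call. = FALSE)
  }
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  required <- c("protein1", "protein2", "combined_score")
  miss <- setdiff(required, names(d))
  if (length(miss) > 0L) {
    stop("StringDB file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  pre <- paste0("^", species_code, "\\.")
  d$protein1 <- sub(pre, "", d$protein1)
  d$protein2 <- sub(pre, "", d$protein2)
  d <- d[d$combined_score >= min_confidence, required, drop = FALSE]
  if (nrow(d) == 0L) {
    stop(sprintf("no edge reaches combined_score >= %d", as.integer(min_confidence)),
         call. = FALSE)
  }
  build_graph(d)
}

#' Parse a BioGRID tab-delimited interaction file
#'
#' Extracts the two official-symbol interactor columns, drops
#' self-interactions and duplicates, and returns the undirected symbol graph.
#' Symbols are preserved verbatim (no case folding).
#'
#' @param path Path to the tab-delimited file.
#' @return An igraph object.
#' @export
parse_biogrid <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("Official Symbol Interactor A", "Official Symbol Interactor B")
  miss <- setdiff(required, names(d))
  if (length(miss) > 0L) {
    stop("BioGRID file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(d) == 0L) {
    stop("BioGRID file has a header but no interaction rows", call. = FALSE)
  }
  build_graph(d[, required, drop = FALSE])
}

#' Load a gene/protein expression vector from a two-column file
#'
#' Reads `identifier<TAB>value` lines (whitespace also accepted); a header is
#' auto-detected by a non-numeric second field on the first line. With
#' `log2_transform` (the default), values become `log2(E + 1)` — the
#' pseudocount keeps zero counts finite on the log scale. Values that are
#' non-positive after transformation are retained but listed in the
#' `"flagged"` attribute; [network_potential()] requires strictly positive
#' weights, so flagged nodes must be dropped before scoring (see
#' [gfilter_by_value()]).
#'
#' @param path Path to the expression file.
#' @param log2_transform Apply `log2(E + 1)`. Default `TRUE`.
#' @return Named numeric vector with attribute `flagged` (identifiers whose
#'   value is `<= 0`).
#' @export
load_expression <- function(path, log2_transform = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("expression file is empty", call. = FALSE)
  split_line <- function(x) {
    parts <- strsplit(x, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) parts <- strsplit(trimws(x), "\\s+")[[1L]]
    parts
  }
  first <- split_line(lines[[1L]])
  has_header <- length(first) >= 2L &&
    is.na(suppressWarnings(as.numeric(first[[2L]])))
  body <- if (has_header) lines[-1L] else lines
  if (length(body) == 0L) stop("expression file has no data rows", call. = FALSE)
  ids <- character(length(body))
  vals <- numeric(length(body))
  for (k in seq_along(body)) {
    parts <- split_line(body[[k]])
    line_no <- k + as.integer(has_header)
    if (length(parts) < 2L) {
      stop(sprintf("expression file line %d: expected two fields", line_no),
           call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(parts[[2L]]))
    if (is.na(v)) {
      stop(sprintf("expression file line %d: value '%s' is not numeric",
                   line_no, parts[[2L]]), call. = FALSE)
    }
    ids[[k]] <- parts[[1L]]
    vals[[k]] <- v
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate identifier(s) in expression file: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (log2_transform) vals <- log2(vals + 1)
  names(vals) <- ids
  attr(vals, "flagged") <- ids[vals <= 0]
  vals
}

# ---- caching -----------------------------------------------------------

cache_file <- function(cache, repository, species_code) {
  file.path(cache, sprintf("%s_%s_edges.tsv.gz", repository, species_code))
}

#' Write a graph to a gzipped edge-list cache file
#'
#' The cache format is a plain gzipped TSV (`node_a`, `node_b`
#' \[, `confidence`\]): portable, inspectable and diff-able.
#'
#' @param g An igraph object.
#' @param path Output path (conventionally `*.tsv.gz`).
#' @return `path`, invisibly.
#' @export
write_graph_cache <- function(g, path) {
  con <- gzfile(path, "w")
  on.exit(close(con))
  utils::write.table(graph_edge_table(g), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a graph from a gzipped edge-list cache file
#'
#' Fails loudly (naming the file) if the cache does not parse as a two- or
#' three-column edge list; a corrupt cache is never silently refetched.
#'
#' @param path Cache file path.
#' @return An igraph object.
#' @export
read_graph_cache <- function(path) {
  d <- tryCatch(utils::read.delim(gzfile(path), stringsAsFactors = FALSE),
                error = function(e) NULL)
  ok <- !is.null(d) && ncol(d) >= 2L && nrow(d) >= 1L &&
    all(c("node_a", "node_b") %in% names(d))
  if (!ok) {
    stop("corrupt or unreadable cache file: ", path, call. = FALSE)
  }
  build_graph(d)
}

default_ppi_url <- function(repository, species_code) {
  switch(repository,
    stringdb = sprintf(
      "https://stringdb-downloads.org/download/protein.links.v12.0/%s.protein.links.v12.0.txt.gz",
      species_code),
    biogrid = "https://downloads.thebiogrid.org/Download/BioGRID/Latest-Release/BIOGRID-ORGANISM-Homo_sapiens-LATEST.tab3.zip",
    stop("unknown repository: ", repository, call. = FALSE))
}

#' Load a protein-protein interaction network
#'
#' Returns the requested PPI graph, preferring a local cache: when a cache
#' file for (`repository`, `species_code`) exists under `cache` it is loaded
#' with no network access; otherwise the repository is fetched over HTTP,
#' parsed, and (when `cache` is set) persisted as a gzipped edge-list TSV so
#' later calls are offline. A local file can stand in for the download via
#' `path`.
#'
#' @param repository `"stringdb"` or `"biogrid"`.
#' @param species_code Taxonomy code (StringDB namespace). Default human,
#'   `"9606"`.
#' @param min_confidence StringDB combined_score threshold (ignored for
#'   BioGRID). Default 400.
#' @param cache Optional directory for the cache file.
#' @param path Optional local file in the repository's dialect, used instead
#'   of downloading.
#' @return An igraph object.
#' @export
load_ppi <- function(repository = c("stringdb", "biogrid"),
                     species_code = "9606", min_confidence = 400L,
                     cache = NULL, path = NULL) {
  repository <- match.arg(repository)
  if (!is.null(cache)) {
    cf <- cache_file(cache, repository, species_code)
    if (file.exists(cf)) {
      return(read_graph_cache(cf))
    }
  }
  if (is.null(path)) {
    url <- default_ppi_url(repository, species_code)
    tmp <- tempfile(fileext = ".gz")
    ok <- tryCatch(
      utils::download.file(url, tmp, mode = "wb", quiet = TRUE) == 0L,
      error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) {
      stop("no cached PPI and the download failed; supply a local file via ",
           "the 'path' argument or populate the cache", call. = FALSE)
    }
    path <- tmp
  }
  g <- switch(repository,
    stringdb = parse_stringdb_links(path, min_confidence, species_code),
    biogrid = parse_biogrid(path))
  if (!is.null(cache)) {
    dir.create(cache, showWarnings = FALSE, recursive = TRUE)
    write_graph_cache(g, cache_file(cache, repository, species_code))
  }
  g
}
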