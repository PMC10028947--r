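# Independent oracles and small fixture builders used across the suite.
# Every oracle here deliberately avoids the code path it checks.

# Graph from a two-column character matrix of edges.
tiny_graph <- function(...) {
  e <- matrix(c(...), ncol = 2, byrow = TRUE)
  build_graph(data.frame(a = e[, 1], b = e[, 2], stringsAsFactors = FALSE))
}

# Seeded Erdos-Renyi graph guaranteed to have at least one edge; returns the
# graph plus a set of non-isolated candidate seeds.
random_test_graph <- function(n, p, seed) {
  repeat {
    g <- make_graph("erdos_renyi", n_nodes = n, param = p, rng_seed = seed)
    deg <- igraph::degree(g)
    if (igraph::ecount(g) >= 1L && sum(deg > 0) >= 2L) {
      return(list(graph = g, candidates = names(deg)[deg > 0]))
    }
    seed <- seed + 1000L
  }
}

# Brute-force Benjamini-Hochberg step-up from the definition:
# adj_(i) = min_{j >= i} min(1, m * p_(j) / j), in the order of sorted p.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  raw <- pmin(1, m * ps / seq_len(m))
  adj_sorted <- rev(cummin(rev(raw)))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  names(adj) <- names(p)
  adj
}

# Brute-force Holm step-down: adj_(i) = max_{j <= i} min(1, (m - j + 1) p_(j)).
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  raw <- pmin(1, (m - seq_len(m) + 1) * ps)
  adj_sorted <- cummax(raw)
  adj <- numeric(m)
  adj[o] <- adj_sorted
  names(adj) <- names(p)
  adj
}

# Exhaustive betweenness oracle: hand-rolled BFS distances and shortest-path
# counts; pairs (s, t) with s < t contribute sigma_st(v)/sigma_st where
# sigma_st(v) = sigma_s(v) * sigma_t(v) when v lies on a shortest s-t path.
betweenness_oracle <- function(g) {
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  adj <- lapply(igraph::as_adj_list(g), function(vs) as.integer(vs))
  bfs_counts <- function(s) {
    dist <- rep(Inf, n)
    sigma <- numeric(n)
    dist[s] <- 0
    sigma[s] <- 1
    queue <- s
    while (length(queue) > 0L) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      for (v in adj[[u]]) {
        if (is.infinite(dist[v])) {
          dist[v] <- dist[u] + 1
          queue <- c(queue, v)
        }
        if (dist[v] == dist[u] + 1) sigma[v] <- sigma[v] + sigma[u]
      }
    }
    list(dist = dist, sigma = sigma)
  }
  info <- lapply(seq_len(n), bfs_counts)
  score <- numeric(n)
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      d_st <- info[[s]]$dist[t]
      if (is.infinite(d_st)) next
      sig_st <- info[[s]]$sigma[t]
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (info[[s]]$dist[v] + info[[t]]$dist[v] == d_st) {
          score[v] <- score[v] +
            info[[s]]$sigma[v] * info[[t]]$sigma[v] / sig_st
        }
      }
    }
  }
  names(score) <- nodes
  score
}

# Full-recompute repression oracle: rebuild the graph without the target and
# re-score every node from scratch. Returns the per-node delta column over
# the (sorted) original node set, with the removed node's own score at its
# position, plus the global delta S.
repression_oracle <- function(g, weights, target) {
  nodes <- sort(igraph::V(g)$name)
  s <- network_potential(g, weights)
  g2 <- igraph::delete_vertices(g, target)
  s2 <- network_potential(g2, weights)
  col <- numeric(length(nodes))
  names(col) <- nodes
  others <- setdiff(nodes, target)
  col[others] <- s[others] - s2[others]
  col[target] <- s[[target]]
  list(column = col, delta_S = sum(s) - sum(s2))
}
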