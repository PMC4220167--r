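# Brute-force centrality oracle: enumerates every shortest path between
# every node pair and counts interior occurrences. Independent of the
# package's Brandes-style implementations; feasible up to ~30 nodes.
oracle_centralities <- function(network) {
  g <- network$graph
  ids <- igraph::V(g)$name
  n <- length(ids)
  bc <- stats::setNames(numeric(n), ids)
  st <- bc
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      paths <- igraph::all_shortest_paths(g, from = s, to = t)$res
      interior <- unlist(lapply(paths, function(p) setdiff(as.integer(p), c(s, t))))
      if (length(interior)) {
        counts <- table(interior)
        v <- ids[as.integer(names(counts))]
        st[v] <- st[v] + as.numeric(counts)
        bc[v] <- bc[v] + as.numeric(counts) / length(paths)
      }
    }
  }
  list(bc = bc, stress = st)
}

# Random connected Erdos-Renyi graph wrapped as an interaction_network.
random_connected_network <- function(n, p = 0.15, seed = 1) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("v%03d", seq_len(n))
  structure(list(graph = g, name = "random", provenance = ""),
            class = "interaction_network")
}

# Path / cycle / star / complete test graphs.
path_network <- function(ids) {
  n <- length(ids)
  interaction_network(cbind(ids[-n], ids[-1]))
}
cycle_network <- function(ids) {
  n <- length(ids)
  interaction_network(cbind(ids, ids[c(2:n, 1)]))
}
star_network <- function(n_leaves) {
  interaction_network(cbind("hub", sprintf("leaf%02d", seq_len(n_leaves))))
}
complete_network <- function(n) {
  ids <- sprintf("k%02d", seq_len(n))
  interaction_network(t(utils::combn(ids, 2)))
}

# Kolmogorov-Smirnov distance of a sample to Uniform(0, 1), computed
# directly so ties do not matter.
ks_uniform <- function(p) {
  p <- sort(p)
  n <- length(p)
  max(abs(seq_len(n) / n - p), abs((seq_len(n) - 1) / n - p))
}

# Benjamini-Hochberg step-up, written from the definition for use as an
# independent check against p.adjust-based code paths.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}
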