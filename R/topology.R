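#' Degree of every node
#'
#' Degree is the number of edges attached to a node, equal to the number of
#' distinct neighbours on a simple undirected graph.
#'
#' @param network an `interaction_network`.
#' @return Named integer vector over all nodes.
#' @export
degree_centrality <- function(network) {
  d <- igraph::degree(network$graph, loops = FALSE)
  storage.mode(d) <- "integer"
  d
}

#' Betweenness centrality
#'
#' Unnormalized betweenness on an unweighted undirected graph:
#' \deqn{BC(v) = \sum_{s < t,\; s \ne v \ne t} \sigma_{st}(v) / \sigma_{st}}
#' where \eqn{\sigma_{st}} counts shortest s--t paths and
#' \eqn{\sigma_{st}(v)} those passing through v. Endpoints are excluded from
#' their own counts. Values are raw pair-fraction sums; within one network a
#' normalization is a constant factor, so ranks are unaffected. Set
#' `normalized = TRUE` to divide by \eqn{(n-1)(n-2)/2} for cross-network
#' display.
#'
#' @param network an `interaction_network`; must be connected (pass the
#'   [main_component()]).
#' @param normalized divide by the number of node pairs excluding v.
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(network, normalized = FALSE) {
  stopifnot_connected(network)
  b <- igraph::betweenness(network$graph, directed = FALSE, normalized = FALSE)
  if (normalized) {
    n <- igraph::vcount(network$graph)
    if (n > 2) b <- b / ((n - 1) * (n - 2) / 2)
  }
  b
}

#' Stress centrality
#'
#' Stress sums the absolute number of shortest paths through a node rather
#' than the per-pair fraction:
#' \deqn{S(v) = \sum_{s < t,\; s \ne v \ne t} \sigma_{st}(v)}
#' It is computed by a Brandes-style breadth-first accumulation (one BFS per
#' source, path counts propagated backwards), so it scales to
#' interactome-size graphs while agreeing exactly with explicit
#' all-shortest-path enumeration. On unit-length graphs
#' \eqn{S(v) \ge BC(v)} for every v, since each summed count is at least its
#' fraction.
#'
#' @inheritParams betweenness_centrality
#' @return Named numeric vector of non-negative path counts.
#' @export
stress_centrality <- function(network) {
  stopifnot_connected(network)
  g <- network$graph
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  s <- stress_brandes(n, matrix(as.integer(el - 1L), ncol = 2))
  names(s) <- igraph::V(g)$name
  s
}

stopifnot_connected <- function(network) {
  if (igraph::vcount(network$graph) == 0) stop("empty network")
  if (!igraph::is_connected(network$graph)) {
    stop("network is disconnected; pass the main component")
  }
  invisible(TRUE)
}

#' Percent rank of a numeric vector
#'
#' Excel-style percent rank: the fraction of the other values that are
#' strictly smaller, `(# values < x) / (n - 1)`. The minimum maps to 0, the
#' maximum to 1, and ties share a value. Defined as 0 for a single value.
#'
#' @param values numeric vector, `length(values) >= 1`.
#' @return Numeric vector in `[0, 1]`, same length and names as `values`.
#' @export
percent_rank <- function(values) {
  n <- length(values)
  if (n == 0) stop("percent_rank of empty vector")
  if (n == 1) return(stats::setNames(0, names(values)))
  # rank(ties = "min") - 1 counts the values strictly smaller
  (rank(values, ties.method = "min") - 1) / (n - 1)
}

# Dense descending rank: largest value gets 1, ties share a rank, no gaps.
rank_dense_desc <- function(values) {
  match(values, sort(unique(values), decreasing = TRUE))
}

#' Full centrality table for the main component
#'
#' Computes degree, betweenness and stress for every node of a connected
#' network, together with the dense betweenness rank (1 = largest, ties
#' share the smallest applicable rank) and the percent rank of the degree.
#'
#' @inheritParams betweenness_centrality
#' @return A data frame with columns `node_id`, `degree`, `betweenness`,
#'   `stress`, `bc_rank`, `degree_percent_rank`, ordered by decreasing
#'   betweenness (ties by node ID).
#' @examples
#' nw <- interaction_network(cbind(c("A", "B", "C"), c("B", "C", "D")))
#' centrality_table(nw)
#' @export
centrality_table <- function(network) {
  stopifnot_connected(network)
  deg <- degree_centrality(network)
  bc <- betweenness_centrality(network)
  st <- stress_centrality(network)
  tab <- data.frame(
    node_id = names(deg),
    degree = as.integer(deg),
    betweenness = as.numeric(bc[names(deg)]),
    stress = as.numeric(st[names(deg)]),
    stringsAsFactors = FALSE
  )
  tab$bc_rank <- rank_dense_desc(tab$betweenness)
  tab$degree_percent_rank <- percent_rank(tab$degree)
  tab[order(tab$bc_rank, tab$node_id), , drop = FALSE]
}
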