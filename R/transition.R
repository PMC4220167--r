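#' Construct a directed map with complex-node groups
#'
#' A directed map is a simple digraph (no self-loops, no duplicate arcs)
#' whose nodes may be grouped into complex nodes: a protein together with
#' its modified instance (e.g. a kinase and its phosphorylated form),
#' collapsed into one node for degree computation. Groups must be disjoint.
#'
#' @param arcs two-column character matrix or data frame of ordered
#'   (source, target) pairs.
#' @param nodes optional node IDs beyond those in `arcs`.
#' @param groups named list of character vectors: group ID -> member nodes.
#'   The group ID is used as the collapsed node's ID (conventionally the
#'   base protein), so name groups after the member shared with the
#'   undirected map when classifying transitions.
#' @return A `directed_map` with `$graph` (directed igraph) and `$groups`.
#' @export
directed_map <- function(arcs, nodes = NULL, groups = list()) {
  arcs <- as_edge_matrix(arcs)
  ids <- unique(c(nodes, as.vector(t(arcs))))
  ids <- ids[!is.na(ids) & nzchar(ids)]
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(ids), name = ids)
  if (nrow(arcs)) g <- igraph::add_edges(g, as.vector(t(arcs)))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(members)) stop("complex-node groups must be disjoint")
  if (length(members) && !all(members %in% ids)) {
    stop("group member(s) not in the map: ",
         paste(setdiff(members, ids), collapse = ", "))
  }
  structure(list(graph = g, groups = groups), class = "directed_map")
}

#' Undirected degree of a directed map with complex-node merging
#'
#' Converts directed degrees to the undirected convention used for
#' protein-interaction maps. Each complex-node group is collapsed to a
#' single node whose degree is the number of distinct external endpoints of
#' arcs incident (in either direction) to any member; arcs internal to the
#' group are excluded. An ungrouped node's degree is its number of distinct
#' neighbours ignoring direction, so a reciprocal arc pair contributes one
#' neighbour. This distinct-neighbour definition coincides with summing
#' members' in- plus out-degrees and subtracting every internal arc from
#' both the counts in which it appears; the literal single-subtraction
#' variant (sum of member in+out degrees minus the internal arc count,
#' reciprocal external arcs counted twice) is available as
#' `internal = "literal_subtraction"` for comparison.
#'
#' @param dmap a `directed_map`.
#' @param internal internal-arc handling: `"distinct_external"` (default)
#'   or `"literal_subtraction"`.
#' @return Named integer vector over collapsed node IDs (group IDs for
#'   groups, node IDs otherwise).
#' @export
merged_directed_degree <- function(dmap,
                                   internal = c("distinct_external",
                                                "literal_subtraction")) {
  internal <- match.arg(internal)
  g <- dmap$graph
  ids <- igraph::V(g)$name
  arcs <- igraph::as_edgelist(g, names = TRUE)
  member_of <- stats::setNames(rep(names(dmap$groups), lengths(dmap$groups)),
                               unlist(dmap$groups, use.names = FALSE))
  # collapse: a node's unit is its group ID if grouped, else itself
  unit <- ifelse(ids %in% names(member_of), member_of[ids], ids)
  names(unit) <- ids
  units <- unique(unname(unit))
  deg <- stats::setNames(integer(length(units)), units)
  if (nrow(arcs) == 0) return(deg)
  ua <- unit[arcs[, 1]]
  ub <- unit[arcs[, 2]]
  external <- ua != ub
  if (internal == "distinct_external") {
    for (u in units) {
      inc <- external & (ua == u | ub == u)
      other <- ifelse(ua[inc] == u, ub[inc], ua[inc])
      deg[u] <- length(unique(other))
    }
  } else {
    # sum of member in+out degrees, internal arcs subtracted once each
    for (u in units) {
      n_inc <- sum(ua == u) + sum(ub == u)   # internal arcs counted twice
      n_int <- sum(!external & ua == u)
      deg[u] <- n_inc - n_int
    }
  }
  deg
}

#' Classify node-importance transitions between two maps
#'
#' Percent-ranks the degree within each map (each over that map's full node
#' set), then classifies every node shared by both maps by the change in
#' percent rank from the first (directed, single-omic) to the second
#' (undirected, multi-omic) map: `accomplished` when the rank is preserved
#' within the tolerance, `climber` when it rises by more than the
#' tolerance, `loser` when it falls by more than it. The default tolerance
#' of 0.10 (plus/minus 10 percent-rank points, boundary inclusive) trades
#' exact rank preservation for a biologically informative grouping.
#'
#' @param tr_degrees named numeric vector: degrees in the directed map
#'   after complex-node merging ([merged_directed_degree()]).
#' @param ei_degrees named numeric vector: degrees in the undirected map
#'   ([degree_centrality()]).
#' @param tolerance percent-rank half-width of the accomplished band.
#' @return A `transition_records` data frame with columns `node_id`,
#'   `degree_tr`, `degree_ei`, `prank_tr`, `prank_ei`, `delta_prank`,
#'   `klass`; the per-class counts are in `attr(, "summary")`.
#' @export
classify_transitions <- function(tr_degrees, ei_degrees, tolerance = 0.10) {
  if (is.null(names(tr_degrees)) || is.null(names(ei_degrees))) {
    stop("degree vectors must be named by node ID")
  }
  shared <- intersect(names(tr_degrees), names(ei_degrees))
  if (length(shared) == 0) stop("the two maps share no node")
  prank_tr <- percent_rank(tr_degrees)
  prank_ei <- percent_rank(ei_degrees)
  delta <- as.numeric(prank_ei[shared] - prank_tr[shared])
  klass <- ifelse(abs(delta) <= tolerance, "accomplished",
                  ifelse(delta > tolerance, "climber", "loser"))
  rec <- data.frame(
    node_id = shared,
    degree_tr = as.numeric(tr_degrees[shared]),
    degree_ei = as.numeric(ei_degrees[shared]),
    prank_tr = as.numeric(prank_tr[shared]),
    prank_ei = as.numeric(prank_ei[shared]),
    delta_prank = delta,
    klass = klass,
    stringsAsFactors = FALSE
  )
  rec <- rec[order(rec$node_id), , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "summary") <- c(
    accomplished = sum(klass == "accomplished"),
    climber = sum(klass == "climber"),
    loser = sum(klass == "loser")
  )
  attr(rec, "tolerance") <- tolerance
  class(rec) <- c("transition_records", "data.frame")
  rec
}

#' Export per-class gene lists
#'
#' Writes one plain-text ID list per class (`accomplished.txt`,
#' `climbers.txt`, `losers.txt`), sorted, one ID per line, for downstream
#' enrichment tools. Empty classes still produce an (empty) file, and
#' reruns are byte-identical.
#'
#' @param records a `transition_records` data frame.
#' @param dir output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
export_class_lists <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(accomplished = file.path(dir, "accomplished.txt"),
             climber = file.path(dir, "climbers.txt"),
             loser = file.path(dir, "losers.txt"))
  for (cls in names(files)) {
    ids <- sort(records$node_id[records$klass == cls])
    writeLines(ids, files[[cls]])
  }
  invisible(files)
}

#' Read/write complex-node grouping tables
#'
#' Grouping TSV: two columns `group_id`, `member_id`, one member per row.
#'
#' @param path file path.
#' @return `read_groups_tsv()`: named list of member vectors.
#' @export
read_groups_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  if (!all(c("group_id", "member_id") %in% colnames(tab))) {
    stop("grouping file needs group_id and member_id columns")
  }
  split(tab$member_id, tab$group_id)
}

#' @rdname read_groups_tsv
#' @param groups named list of member vectors.
#' @export
write_groups_tsv <- function(groups, path) {
  tab <- data.frame(
    group_id = rep(names(groups), lengths(groups)),
    member_id = unlist(groups, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
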