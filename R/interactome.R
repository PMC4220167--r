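#' Construct an interaction network
#'
#' An `interaction_network` is a simple undirected graph over molecule IDs:
#' no self-loops, no duplicate edges, every edge endpoint present in the node
#' set. Nodes without any retained edge are kept and flagged as isolated;
#' topology computations exclude them by operating on the main connected
#' component (see [main_component()]).
#'
#' @param edges two-column character matrix or data frame of edge endpoints.
#'   Order within a row is ignored (edges are undirected); self-loops are
#'   dropped and duplicates collapsed.
#' @param nodes optional character vector of node IDs; defaults to the IDs
#'   appearing in `edges`. IDs in `nodes` with no edge become isolated nodes.
#' @param name short label for the network.
#' @param provenance free-text provenance note.
#' @return An object of class `interaction_network` wrapping an
#'   [igraph::igraph] graph (`$graph`) plus `$name` and `$provenance`.
#' @examples
#' nw <- interaction_network(cbind(c("A", "B"), c("B", "C")), nodes = c("A", "B", "C", "D"))
#' network_nodes(nw)
#' isolated_nodes(nw)
#' @export
interaction_network <- function(edges, nodes = NULL, name = "", provenance = "") {
  edges <- as_edge_matrix(edges)
  ids <- unique(c(nodes, as.vector(t(edges))))
  ids <- ids[!is.na(ids) & nzchar(ids)]
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids)
  if (nrow(edges)) g <- igraph::add_edges(g, as.vector(t(edges)))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  structure(list(graph = g, name = name, provenance = provenance),
            class = "interaction_network")
}

# Normalize edge input to a 2-column character matrix (may be 0-row).
as_edge_matrix <- function(edges) {
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0)) {
    return(matrix(character(0), ncol = 2))
  }
  if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2, drop = FALSE])
  if (!is.matrix(edges)) stop("edges must be a 2-column matrix or data frame")
  if (ncol(edges) < 2) stop("edges must have two columns")
  mode(edges) <- "character"
  edges[, 1:2, drop = FALSE]
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %s: %d nodes, %d edges (%d isolated)\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              length(isolated_nodes(x))))
  invisible(x)
}

#' Node, edge and isolation accessors
#'
#' @param network an `interaction_network`.
#' @return `network_nodes()`: character vector of node IDs.
#'   `network_edges()`: two-column character matrix, one row per undirected
#'   edge, endpoints sorted within each row. `isolated_nodes()`: IDs of nodes
#'   with no incident edge.
#' @export
network_nodes <- function(network) {
  igraph::V(network$graph)$name
}

#' @rdname network_nodes
#' @export
network_edges <- function(network) {
  e <- igraph::as_edgelist(network$graph, names = TRUE)
  if (nrow(e)) {
    swap <- e[, 1] > e[, 2]
    e[swap, ] <- e[swap, c(2, 1), drop = FALSE]
    e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  }
  colnames(e) <- c("node_a", "node_b")
  e
}

#' @rdname network_nodes
#' @export
isolated_nodes <- function(network) {
  d <- igraph::degree(network$graph)
  names(d)[d == 0]
}

#' Induce an interactome from a node catalog and an edge table
#'
#' Retains only edges whose both endpoints are catalogued molecules, drops
#' self-loops, collapses duplicate rows (including reversed duplicates), and
#' keeps edge-less catalog nodes as isolated nodes. This mirrors how curated
#' molecule lists are intersected with a protein-interaction database: many
#' catalog entries have no recorded interaction and remain isolated, and the
#' subsequent topology runs on the main connected component only.
#'
#' @param catalog a `node_catalog` (see [merge_subsets()]) or a character
#'   vector of molecule IDs.
#' @param edge_table two-column edge table (matrix or data frame); self-loops
#'   and duplicates are allowed in the input.
#' @param name,provenance passed to [interaction_network()].
#' @return An `interaction_network` whose node set equals the catalog.
#' @export
induce_interactome <- function(catalog, edge_table, name = "interactome",
                               provenance = "induced from catalog") {
  ids <- catalog_ids(catalog)
  edges <- as_edge_matrix(edge_table)
  keep <- edges[, 1] %in% ids & edges[, 2] %in% ids
  interaction_network(edges[keep, , drop = FALSE], nodes = ids,
                      name = name, provenance = provenance)
}

catalog_ids <- function(catalog) {
  if (inherits(catalog, "node_catalog")) catalog$node_id else as.character(catalog)
}

#' Extract the main connected component
#'
#' Returns the subnetwork on the largest connected component, the unit on
#' which all centrality computations run (isolated molecules and minor
#' components carry no shortest-path information). Size ties are broken by
#' the component containing the lexicographically smallest member ID.
#'
#' @param network an `interaction_network`.
#' @return An `interaction_network` restricted to the main component.
#' @export
main_component <- function(network) {
  if (igraph::vcount(network$graph) == 0) stop("empty network")
  comp <- igraph::components(network$graph)
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1) {
    # smallest lexicographic member decides among equal-sized components
    firsts <- vapply(cand, function(k) {
      min(igraph::V(network$graph)$name[comp$membership == k])
    }, character(1))
    cand <- cand[order(firsts)[1]]
  }
  keep <- which(comp$membership == cand[1])
  sub <- igraph::induced_subgraph(network$graph, keep)
  structure(list(graph = sub, name = network$name,
                 provenance = paste0(network$provenance, "; main component")),
            class = "interaction_network")
}

#' Read and write networks in standard graph formats
#'
#' Supported formats: `"tsv"` (two-column edge table, one edge per line,
#' tab-separated; isolated nodes appear as a single-field line), `"sif"`
#' (Cytoscape simple interaction format, `A <type> B`; the interaction type
#' is preserved on read as edge attribute `type` but ignored by all
#' algorithms), and `"graphml"` (via igraph). `write_graph_file()` followed
#' by `read_graph_file()` is the identity on the (nodes, edges) pair; node
#' order is not guaranteed.
#'
#' @param path file path.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`.
#' @param network an `interaction_network`.
#' @return `read_graph_file()` returns an `interaction_network`;
#'   `write_graph_file()` returns `path` invisibly.
#' @export
read_graph_file <- function(path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read graph file: ", path)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(igraph::simplify(g), mode = "collapse")
    nw <- structure(list(graph = g, name = "", provenance = path),
                    class = "interaction_network")
    return(nw)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  edges <- matrix(character(0), ncol = 2)
  singles <- character(0)
  types <- character(0)
  for (i in seq_along(lines)) {
    if (format == "tsv") {
      f <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
      # a line without any tab is an isolated-node record
      if (!grepl("\t", lines[i], fixed = TRUE) && length(f) == 1 && nzchar(f)) {
        singles <- c(singles, f)
        next
      }
      if (length(f) < 2 || any(!nzchar(f[1:2]))) {
        stop(sprintf("malformed edge row at line %d: '%s'", i, lines[i]))
      }
      edges <- rbind(edges, f[1:2])
    } else {
      f <- strsplit(trimws(lines[i]), "[\t ]+")[[1]] # sif: source [type target1 target2 ...] ; bare node line allowed
      if (length(f) == 1) { singles <- c(singles, f); next }
      if (length(f) < 3) {
        stop(sprintf("malformed SIF row at line %d: '%s'", i, lines[i]))
      }
      for (t in f[3:length(f)]) {
        edges <- rbind(edges, c(f[1], t))
        types <- c(types, f[2])
      }
    }
  }
  nw <- interaction_network(edges, nodes = c(as.vector(edges), singles),
                            provenance = path)
  nw
}

#' @rdname read_graph_file
#' @export
write_graph_file <- function(network, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network$graph, path, format = "graphml")
    return(invisible(path))
  }
  e <- network_edges(network)
  iso <- sort(isolated_nodes(network))
  lines <- character(0)
  if (nrow(e)) {
    lines <- if (format == "tsv") paste(e[, 1], e[, 2], sep = "\t")
             else paste(e[, 1], "pp", e[, 2], sep = "\t")
  }
  writeLines(c(lines, iso), path)
  invisible(path)
}
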