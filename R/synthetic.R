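#' Configuration of the synthetic multi-omic study
#'
#' Bundles every parameter of the synthetic-data generators. The defaults
#' reproduce the shape of the multi-omic rheumatoid-arthritis study the
#' pipeline is designed around: a heavy-tailed undirected interactome of
#' 3466 nodes and 24364 edges (the extended interactome's main cluster), a
#' catalog of 13 data sources (19 subset IDs once the pathway-expansion and
#' expression sources are split) merged into 8 districts, a directed
#' transcriptional sub-map of 302 nodes containing protein/modified-protein
#' complex nodes, a 20-node drug-target set, and a log2 microarray-style
#' expression matrix with 2 control and 2 case samples.
#'
#' Every generator is a pure function of (config, seed): the same seed
#' yields byte-identical outputs. Each generator draws from its own RNG
#' stream (`seed + a fixed per-generator offset`), so e.g. regenerating the
#' expression matrix does not disturb the network.
#'
#' @param n_nodes,n_edges size of the undirected network.
#' @param degree_model `"preferential_attachment"` (default; heavy-tailed,
#'   like protein-interaction maps) or `"configuration"` (power-law-fitness
#'   configuration-style null with the same node and edge counts).
#' @param n_subsets number of data sources (13 in the emulated study).
#' @param subset_sizes optional vector of subset sizes; named by subset ID
#'   (IDs must be in [district_map()]), or unnamed to use the canonical IDs
#'   in order. `NULL` uses the study's source sizes scaled to the molecule
#'   universe.
#' @param subset_overlap fraction of each subset drawn from molecules
#'   already covered by earlier subsets. The default 0.51 is the overlap
#'   implied by the emulated study's subset sizes (summing to roughly twice
#'   the union).
#' @param extra_molecule_fraction catalogued molecules with no interaction
#'   record, as a fraction of `n_nodes`; they appear in the catalog but
#'   stay isolated in the induced interactome (default 0.25, the study's
#'   catalog-to-interactome attrition).
#' @param directed_map_size nodes of the directed sub-map.
#' @param n_complex_nodes protein + modified-instance pairs in the directed
#'   map; each pair is one complex node of 2 members.
#' @param target_set_size drug-target set size (default 20).
#' @param expr_n_probes expression probes (default 1000).
#' @param expr_groups sample counts of the two expression groups
#'   (default 2, 2).
#' @param planted_log2fc absolute log2 fold change planted in
#'   differentially expressed genes (default 1.2).
#' @param planted_fraction fraction of genes carrying the planted effect
#'   (default 0.1).
#' @param planted_down_fraction fraction of planted genes that are
#'   down-regulated (default 0.68, the down/total ratio of the emulated
#'   microarray comparison).
#' @param noise_sd per-measurement Gaussian noise SD on the log2 scale
#'   (default 0.1).
#' @param seed master seed for all generators.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_nodes = 3466, n_edges = 24364,
                             degree_model = c("preferential_attachment",
                                              "configuration"),
                             n_subsets = 13, subset_sizes = NULL,
                             subset_overlap = 0.51,
                             extra_molecule_fraction = 0.25,
                             directed_map_size = 302, n_complex_nodes = 10,
                             target_set_size = 20,
                             expr_n_probes = 1000, expr_groups = c(2, 2),
                             planted_log2fc = 1.2, planted_fraction = 0.1,
                             planted_down_fraction = 0.68,
                             noise_sd = 0.1, seed = 1) {
  degree_model <- match.arg(degree_model)
  if (n_nodes < 2) stop("n_nodes must be >= 2")
  if (n_edges < 1) stop("n_edges must be >= 1")
  if (n_edges > n_nodes * (n_nodes - 1) / 2) {
    stop("infeasible edge count: a simple graph on ", n_nodes,
         " nodes has at most ", n_nodes * (n_nodes - 1) / 2, " edges")
  }
  if (!is.null(subset_sizes) && any(subset_sizes > n_nodes * (1 + extra_molecule_fraction) + 1)) {
    stop("subset sizes must not exceed the molecule universe")
  }
  if (subset_overlap < 0 || subset_overlap > 1) stop("subset_overlap in [0,1]")
  if (directed_map_size > n_nodes) stop("directed_map_size must be <= n_nodes")
  if (n_complex_nodes < 0) stop("n_complex_nodes must be >= 0")
  if (2 * n_complex_nodes > directed_map_size) {
    stop("n_complex_nodes x 2 exceeds directed_map_size")
  }
  if (target_set_size >= n_nodes) stop("target_set_size must be < n_nodes")
  if (length(expr_groups) != 2 || any(expr_groups < 2)) {
    stop("expr_groups must be two group sizes, each >= 2")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(
    n_nodes = as.integer(n_nodes), n_edges = as.integer(n_edges),
    degree_model = degree_model, n_subsets = as.integer(n_subsets),
    subset_sizes = subset_sizes, subset_overlap = subset_overlap,
    extra_molecule_fraction = extra_molecule_fraction,
    directed_map_size = as.integer(directed_map_size),
    n_complex_nodes = as.integer(n_complex_nodes),
    target_set_size = as.integer(target_set_size),
    expr_n_probes = as.integer(expr_n_probes),
    expr_groups = as.integer(expr_groups),
    planted_log2fc = planted_log2fc, planted_fraction = planted_fraction,
    planted_down_fraction = planted_down_fraction,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Run `expr` under a generator-specific RNG stream, leaving the caller's
# RNG state untouched.
with_generator_seed <- function(seed, offset, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed + offset)
  expr
}

# Source sizes of the emulated study's 19 catalog subsets, used to scale
# default synthetic subset sizes (union of all subsets: 4709 molecules).
canonical_subset_sizes <- function() {
  c("1" = 223, "2" = 49, "3" = 53, "4" = 37, "5" = 54, "6" = 16,
    "3A" = 1248, "3B" = 283, "3C" = 1536, "3D" = 472, "3E" = 1837,
    "7" = 212, "8" = 1652, "9A" = 451, "9B" = 210, "10" = 152,
    "11" = 569, "12" = 364, "13" = 171)
}

#' Generate a synthetic undirected interactome
#'
#' Builds a simple undirected graph with exactly `n_nodes` nodes and
#' `n_edges` edges. Under `"preferential_attachment"` nodes attach
#' preferentially to high-degree nodes, producing the heavy-tailed degree
#' distribution characteristic of protein-interaction maps (for
#' `n_nodes >= 500` the maximum degree is at least 5 times the median).
#' Under `"configuration"` edges are drawn by a power-law-fitness
#' configuration-style model with the same counts, for null comparisons.
#' Node IDs are `N0001`, `N0002`, ...
#'
#' @param config a `synthetic_config`.
#' @return An `interaction_network`.
#' @export
generate_network <- function(config) {
  with_generator_seed(config$seed, 0L, {
    n <- config$n_nodes
    E <- config$n_edges
    g <- if (config$degree_model == "preferential_attachment") {
      # out.seq: edges brought in by each arriving node; node i can attach
      # to at most i-1 earlier nodes
      k <- integer(n)
      rem <- E
      for (i in 2:n) {
        need <- ceiling(rem / (n - i + 1))
        k[i] <- min(i - 1, need)
        rem <- rem - k[i]
      }
      i <- n
      while (rem > 0) {                      # spread any remainder backwards
        add <- min(i - 1 - k[i], rem)
        k[i] <- k[i] + add
        rem <- rem - add
        i <- i - 1
      }
      igraph::sample_pa(n, out.seq = k, directed = FALSE,
                        algorithm = "psumtree")
    } else {
      fitness <- (seq_len(n))^(-0.8)         # power-law expected degrees
      igraph::sample_fitness(E, fitness, loops = FALSE, multiple = FALSE)
    }
    igraph::V(g)$name <- sprintf("N%04d", seq_len(n))
    structure(list(graph = g, name = "synthetic",
                   provenance = sprintf("generated (%s, seed %d)",
                                        config$degree_model, config$seed)),
              class = "interaction_network")
  })
}

# Molecule universe: network nodes plus catalogued molecules with no
# interaction record (IDs X0001, ...).
molecule_universe <- function(config, network) {
  extra <- round(config$extra_molecule_fraction * config$n_nodes)
  c(network_nodes(network),
    if (extra > 0) sprintf("X%04d", seq_len(extra)))
}

#' Generate a synthetic node catalog
#'
#' Draws overlapping molecule subsets from the universe of network nodes
#' plus a configured fraction of interaction-less molecules, and merges
#' them into a `node_catalog` with district annotation. For each subset,
#' a `subset_overlap` fraction of members is drawn from molecules already
#' covered by earlier subsets (when available) and the rest from uncovered
#' molecules, so the union falls short of the summed sizes by the
#' configured overlap.
#'
#' @param config a `synthetic_config`.
#' @param network the network from [generate_network()].
#' @return A `node_catalog`.
#' @export
generate_catalog <- function(config, network) {
  with_generator_seed(config$seed, 1L, {
    universe <- molecule_universe(config, network)
    sizes <- config$subset_sizes
    if (is.null(sizes)) {
      canon <- canonical_subset_sizes()
      sizes <- stats::setNames(pmax(1, round(canon * length(universe) / 4709)),
                               names(canon))
    } else if (is.null(names(sizes))) {
      names(sizes) <- names(canonical_subset_sizes())[seq_along(sizes)]
    }
    if (any(sizes > length(universe))) {
      stop("subset size exceeds the molecule universe")
    }
    covered <- character(0)
    uncovered <- universe
    subsets <- list()
    for (id in names(sizes)) {
      s <- sizes[[id]]
      n_old <- min(round(s * config$subset_overlap), length(covered))
      n_new <- min(s - n_old, length(uncovered))
      n_old <- min(s - n_new, length(covered))   # overflow back if short
      members <- c(if (n_old > 0) sample(covered, n_old),
                   if (n_new > 0) sample(uncovered, n_new))
      subsets[[id]] <- members
      covered <- union(covered, members)
      uncovered <- setdiff(uncovered, members)
    }
    merge_subsets(subsets)
  })
}

#' Generate a synthetic directed sub-map
#'
#' Emulates a directed transcriptional-regulation map sharing nodes with
#' the undirected network. `n_complex_nodes` of its nodes are proteins
#' paired with a modified instance (ID suffix `_p`, e.g. a phosphorylated
#' form): each pair forms one complex-node group of 2 members named after
#' the base protein, connected by at least one internal arc. The map has
#' `directed_map_size` nodes in total (modified instances included) and a
#' mean total degree of about 4.
#'
#' @param config a `synthetic_config`.
#' @param network the network from [generate_network()].
#' @return A `directed_map`.
#' @export
generate_directed_map <- function(config, network) {
  with_generator_seed(config$seed, 2L, {
    size <- config$directed_map_size
    n_cx <- config$n_complex_nodes
    n_shared <- size - n_cx
    base <- sort(sample(network_nodes(network), n_shared))
    cx_base <- if (n_cx > 0) sample(base, n_cx) else character(0)
    modified <- if (n_cx > 0) paste0(cx_base, "_p") else character(0)
    nodes <- c(base, modified)
    n_arcs <- round(2 * size)
    # uniform random ordered pairs, self-loops excluded, duplicates collapse
    from <- sample(nodes, n_arcs, replace = TRUE)
    to <- sample(nodes, n_arcs, replace = TRUE)
    keep <- from != to
    arcs <- cbind(from[keep], to[keep])
    if (n_cx > 0) arcs <- rbind(arcs, cbind(cx_base, modified))
    groups <- if (n_cx > 0) {
      stats::setNames(mapply(c, cx_base, modified, SIMPLIFY = FALSE,
                             USE.NAMES = FALSE), cx_base)
    } else list()
    directed_map(arcs, nodes = nodes, groups = groups)
  })
}

#' Generate a synthetic drug-target set
#'
#' Samples `target_set_size` nodes uniformly from the main connected
#' component of the network, standing in for a literature-curated drug
#' target list.
#'
#' @param config a `synthetic_config`.
#' @param network the network from [generate_network()].
#' @return Character vector of target node IDs, sorted.
#' @export
generate_targets <- function(config, network) {
  with_generator_seed(config$seed, 4L, {
    mc <- main_component(network)
    sort(sample(network_nodes(mc), config$target_set_size))
  })
}

#' Generate a synthetic log2 expression matrix
#'
#' Probes x samples matrix on the log2 scale with two sample groups
#' (`ctrl_*` reference and `case_*`). A `planted_fraction` of genes
#' carries a planted group difference of exactly `planted_log2fc`
#' (down-regulated in cases with probability `planted_down_fraction`, else
#' up); all values receive Gaussian noise of SD `noise_sd`. About 20% of
#' genes get a second probe with noisier measurements, so probe collapse
#' by highest SD is exercised. At `noise_sd = 0` planted genes show the
#' exact difference and all other genes show exactly 0.
#'
#' @param config a `synthetic_config`.
#' @return Data frame `probe_id`, `gene_id`, then sample columns, with
#'   attributes `groups` (list `a` = reference samples, `b` = case
#'   samples) and `planted` (data frame `gene_id`, `effect`).
#' @export
generate_expression <- function(config) {
  with_generator_seed(config$seed, 3L, {
    n_probes <- config$expr_n_probes
    n_genes <- max(1, round(n_probes / 1.2))
    genes <- sprintf("G%05d", seq_len(n_genes))
    # first one probe per gene, then extra probes on the first genes
    gene_of <- c(genes, genes[seq_len(n_probes - n_genes)])
    probes <- sprintf("P%06d", seq_along(gene_of))
    extra_probe <- c(rep(FALSE, n_genes), rep(TRUE, n_probes - n_genes))
    g1 <- config$expr_groups[1]
    g2 <- config$expr_groups[2]
    samples <- c(sprintf("ctrl_%d", seq_len(g1)),
                 sprintf("case_%d", seq_len(g2)))
    n_planted <- round(config$planted_fraction * n_genes)
    planted <- if (n_planted > 0) sample(genes, n_planted) else character(0)
    sign <- ifelse(stats::runif(length(planted)) < config$planted_down_fraction,
                   -1, 1)
    effect <- stats::setNames(rep(0, n_genes), genes)
    effect[planted] <- sign * config$planted_log2fc
    base <- stats::setNames(stats::rnorm(n_genes, mean = 7, sd = 1.5), genes)
    vals <- matrix(0, nrow = n_probes, ncol = g1 + g2,
                   dimnames = list(probes, samples))
    for (i in seq_len(n_probes)) {
      gene <- gene_of[i]
      mu <- c(rep(base[gene], g1), rep(base[gene] + effect[gene], g2))
      sd_i <- config$noise_sd * if (extra_probe[i]) 2 else 1
      vals[i, ] <- mu + stats::rnorm(g1 + g2, sd = sd_i)
    }
    expr <- data.frame(probe_id = probes, gene_id = gene_of,
                       stringsAsFactors = FALSE)
    expr <- cbind(expr, as.data.frame(vals))
    rownames(expr) <- NULL
    attr(expr, "groups") <- list(a = samples[seq_len(g1)],
                                 b = samples[g1 + seq_len(g2)])
    attr(expr, "planted") <- data.frame(
      gene_id = sort(planted),
      effect = effect[sort(planted)],
      row.names = NULL, stringsAsFactors = FALSE
    )
    expr
  })
}

#' Write/read a synthetic expression matrix as TSV
#'
#' Columns: `probe_id`, `gene_id`, then one column per sample. Group
#' membership is recoverable from the sample-name prefixes (`ctrl_`/
#' `case_`).
#'
#' @param expr expression data frame.
#' @param path file path.
#' @return `path` (write) or the expression data frame (read).
#' @export
write_expression_tsv <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  expr <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = NA, stringsAsFactors = FALSE)
  samples <- sample_columns(expr)
  attr(expr, "groups") <- list(a = grep("^ctrl_", samples, value = TRUE),
                               b = grep("^case_", samples, value = TRUE))
  expr
}

#' Write all synthetic inputs of a configuration to a directory
#'
#' Materializes the full synthetic study: network edge table, node
#' catalog, directed-map arc table and complex-node grouping, target list,
#' expression matrix, and the configuration itself (YAML), so the pipeline
#' can be run purely from files.
#'
#' @param config a `synthetic_config`.
#' @param dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_synthetic_inputs <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  network <- generate_network(config)
  catalog <- generate_catalog(config, network)
  dmap <- generate_directed_map(config, network)
  targets <- generate_targets(config, network)
  expr <- generate_expression(config)
  paths <- c(
    network = file.path(dir, "network.tsv"),
    catalog = file.path(dir, "catalog.tsv"),
    directed_arcs = file.path(dir, "directed_arcs.tsv"),
    groups = file.path(dir, "groups.tsv"),
    targets = file.path(dir, "targets.txt"),
    expression = file.path(dir, "expression.tsv"),
    config = file.path(dir, "config.yaml")
  )
  write_graph_file(network, paths[["network"]], "tsv")
  write_catalog_tsv(catalog, paths[["catalog"]])
  arcs <- igraph::as_edgelist(dmap$graph, names = TRUE)
  writeLines(paste(arcs[, 1], arcs[, 2], sep = "\t"), paths[["directed_arcs"]])
  write_groups_tsv(dmap$groups, paths[["groups"]])
  writeLines(targets, paths[["targets"]])
  write_expression_tsv(expr, paths[["expression"]])
  yaml::write_yaml(unclass(config), paths[["config"]])
  invisible(paths)
}
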