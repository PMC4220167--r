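#' District profile of a node's neighbourhood
#'
#' Summarizes the biochemical districts represented around a focal node
#' (the pie-chart view of a hub's "closer interactome"): counts the
#' catalog-district memberships of all nodes within graph distance
#' `radius` of the focal node, the focal node itself excluded. A node
#' belonging to several districts counts once per district, so fractions
#' are over membership counts, not node counts. `radius = Inf` profiles
#' the whole connected component.
#'
#' @param network an `interaction_network`.
#' @param catalog a `node_catalog` covering the network nodes of interest;
#'   neighbours absent from the catalog are ignored.
#' @param focal_node node ID; must be in the network.
#' @param radius neighbourhood radius (default 1; 0 gives an empty
#'   profile).
#' @return A `district_profile` data frame: `district`, `n_members`,
#'   `fraction`, ordered by decreasing count then district label, with the
#'   focal node in `attr(, "focal_node")`.
#' @export
district_profile <- function(network, catalog, focal_node, radius = 1) {
  if (!focal_node %in% network_nodes(network)) {
    stop("focal node not in network: ", focal_node)
  }
  order <- if (is.infinite(radius)) igraph::vcount(network$graph) else radius
  hood <- igraph::ego(network$graph, order = order, nodes = focal_node)[[1]]
  ids <- setdiff(hood$name, focal_node)
  ids <- intersect(ids, catalog$node_id)
  counts <- stats::setNames(integer(0), character(0))
  if (length(ids)) {
    dd <- unlist(catalog_districts(catalog, ids), use.names = FALSE)
    counts <- table(dd)
  }
  prof <- data.frame(
    district = names(counts),
    n_members = as.integer(counts),
    stringsAsFactors = FALSE
  )
  prof$fraction <- if (nrow(prof)) prof$n_members / sum(prof$n_members)
                   else numeric(0)
  prof <- prof[order(-prof$n_members, prof$district), , drop = FALSE]
  rownames(prof) <- NULL
  attr(prof, "focal_node") <- focal_node
  attr(prof, "radius") <- radius
  class(prof) <- c("district_profile", "data.frame")
  prof
}

#' Default pipeline configuration
#'
#' @return Nested list holding the documented schema of the pipeline
#'   configuration: `seed`, `synthetic` (any [synthetic_config()]
#'   argument), `knockout` (`enabled`, `n_null`, `alpha`), `transition`
#'   (`enabled`, `tolerance`), `expression` (`enabled`, `fc_threshold`)
#'   and `report` (`radius`).
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1,
    synthetic = list(),
    knockout = list(enabled = TRUE, n_null = 100, alpha = 0.05),
    transition = list(enabled = TRUE, tolerance = 0.10),
    expression = list(enabled = TRUE, fc_threshold = 2),
    report = list(radius = 1)
  )
}

validation_error <- function(...) {
  stop(structure(class = c("np_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Merge user config over defaults and validate before any compute.
resolve_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) validation_error("config must be a list or YAML path")
  def <- default_pipeline_config()
  for (sec in names(def)) {
    if (is.list(def[[sec]])) {
      unknown <- setdiff(names(config[[sec]]),
                         c(names(def[[sec]]),
                           names(formals(synthetic_config))))
      if (sec != "synthetic" && length(unknown)) {
        validation_error("unknown key(s) in config section '", sec, "': ",
                         paste(unknown, collapse = ", "))
      }
      def[[sec]] <- utils::modifyList(def[[sec]], config[[sec]] %||% list())
    } else if (!is.null(config[[sec]])) {
      def[[sec]] <- config[[sec]]
    }
  }
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    validation_error("unknown config section(s): ",
                     paste(unknown, collapse = ", "))
  }
  def$synthetic$seed <- def$seed
  # validate synthetic arguments by constructing the config now
  def$synthetic_config <- tryCatch(
    do.call(synthetic_config, def$synthetic),
    error = function(e) validation_error("invalid synthetic parameters: ",
                                         conditionMessage(e))
  )
  if (def$knockout$enabled && def$synthetic_config$target_set_size < 1) {
    validation_error("knockout enabled but target_set_size < 1")
  }
  def
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes the stages in order — synthetic input generation, catalog and
#' interactome assembly, main-component extraction, centrality table,
#' drug-target knockout with permutation null and BH-corrected p-values
#' plus procedure concordance, directed-vs-undirected transition
#' classification, DE filter on the expression matrix, and the district
#' profile of the top-betweenness node — writing every result as TSV plus
#' a YAML manifest (inputs, seed, parameters, package version) into
#' `out_dir`. A run is fully reproducible from its manifest:
#' `run_pipeline(manifest$config, new_dir)` regenerates identical files.
#'
#' @param config configuration list or path to a YAML file; see
#'   [default_pipeline_config()] for the schema. Validated before any
#'   compute.
#' @param out_dir output directory (created; existing files overwritten).
#' @param quiet suppress progress logging to the console (a `run.log`
#'   file is always written).
#' @return Invisibly, a list with the main in-memory results
#'   (`network`, `catalog`, `centrality`, `knockout`, `concordance`,
#'   `transitions`, `de`, `profile`) and `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir, quiet = FALSE) {
  cfg <- resolve_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  logmsg <- function(level, ...) {
    line <- sprintf("[%s] %s %s", level,
                    format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), paste0(...))
    cat(line, "\n", file = log_path, append = TRUE)
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    logmsg("INFO", "stage ", name, " started")
    tryCatch(expr, error = function(e) {
      logmsg("ERROR", "stage ", name, " failed: ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  sc <- cfg$synthetic_config
  res <- list()

  stage("synthesize", {
    res$network <- generate_network(sc)
    res$catalog <- generate_catalog(sc, res$network)
    res$targets <- generate_targets(sc, res$network)
    write_graph_file(res$network, file.path(out_dir, "network.tsv"), "tsv")
    write_catalog_tsv(res$catalog, file.path(out_dir, "catalog.tsv"))
    writeLines(res$targets, file.path(out_dir, "targets.txt"))
  })

  stage("build", {
    res$interactome <- induce_interactome(res$catalog,
                                          network_edges(res$network),
                                          name = "synthetic interactome")
    res$main <- main_component(res$interactome)
    write_graph_file(res$main, file.path(out_dir, "main_component.tsv"), "tsv")
  })

  stage("topology", {
    res$centrality <- centrality_table(res$main)
    write_fixed_tsv(res$centrality, file.path(out_dir, "centrality.tsv"))
  })

  if (cfg$knockout$enabled) stage("knockout", {
    exp <- knockout_experiment(res$main, res$targets,
                               n_null = cfg$knockout$n_null,
                               alpha = cfg$knockout$alpha, seed = cfg$seed)
    ko <- knockout(exp)
    ens <- null_distribution(exp)
    res$knockout <- empirical_pvalues(ko, ens)
    res$concordance <- concordance(ko, knockout(exp, "per_fragment"))
    write_perturbation_tsv(res$knockout, file.path(out_dir, "knockout.tsv"))
    yaml::write_yaml(res$concordance, file.path(out_dir, "concordance.yaml"))
    sig <- res$knockout$node_id[which(res$knockout$significant)]
    writeLines(sort(sig), file.path(out_dir, "significant_nodes.txt"))
  })

  if (cfg$transition$enabled) stage("transition", {
    dmap <- generate_directed_map(sc, res$network)
    tr_deg <- merged_directed_degree(dmap)
    ei_deg <- degree_centrality(res$main)
    res$transitions <- classify_transitions(tr_deg, ei_deg,
                                            tolerance = cfg$transition$tolerance)
    write_fixed_tsv(res$transitions, file.path(out_dir, "transitions.tsv"))
    export_class_lists(res$transitions, file.path(out_dir, "class_lists"))
  })

  if (cfg$expression$enabled) stage("expression", {
    expr <- generate_expression(sc)
    groups <- attr(expr, "groups")
    collapsed <- collapse_probes(expr)
    res$de <- fold_change_filter(collapsed, groups$a, groups$b,
                                 fc_threshold = cfg$expression$fc_threshold)
    writeLines(res$de$up, file.path(out_dir, "de_up.txt"))
    writeLines(res$de$down, file.path(out_dir, "de_down.txt"))
  })

  stage("report", {
    top <- res$centrality$node_id[1]
    res$profile <- district_profile(res$main, res$catalog, top,
                                    radius = cfg$report$radius)
    write_fixed_tsv(as.data.frame(res$profile),
                    file.path(out_dir, "district_profile.tsv"))
    manifest <- list(
      package = "netperturb",
      version = as.character(utils::packageVersion("netperturb")),
      config = cfg[setdiff(names(cfg), "synthetic_config")],
      focal_node = top,
      outputs = sort(unique(c(list.files(out_dir), "manifest.yaml")))
    )
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    res$manifest <- manifest
  })
  logmsg("INFO", "pipeline complete")
  invisible(res)
}

# TSV writer with fixed numeric formatting so reruns are diffable.
write_fixed_tsv <- function(df, path, digits = 10) {
  out <- as.data.frame(df)
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.*g", digits, x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
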