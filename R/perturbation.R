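#' Define a virtual knockout experiment
#'
#' A knockout experiment removes a set of drug-target nodes from a
#' connected interactome and measures the resulting per-node changes in
#' betweenness and stress centrality, assessing significance against a
#' permutation null of random equal-size deletions.
#'
#' @param baseline a connected `interaction_network` (the main component).
#' @param targets character vector of target node IDs; must intersect the
#'   baseline and must not cover it.
#' @param n_null number of random deletions forming the null ensemble
#'   (default 1000).
#' @param null_k nodes removed per null draw; defaults to the number of
#'   targets actually present in the baseline.
#' @param alpha significance threshold on BH-adjusted p-values.
#' @param seed integer seed driving the null draws.
#' @return A `knockout_experiment` list.
#' @export
knockout_experiment <- function(baseline, targets, n_null = 1000,
                                null_k = NULL, alpha = 0.05, seed = 1) {
  stopifnot_connected(baseline)
  present <- intersect(targets, network_nodes(baseline))
  if (length(present) == 0) stop("no target is present in the baseline network")
  if (length(present) >= igraph::vcount(baseline$graph)) {
    stop("targets cover the whole baseline network")
  }
  if (is.null(null_k)) null_k <- length(present)
  if (n_null < 1) stop("n_null must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(baseline = baseline, targets = targets,
                 targets_present = present, n_null = as.integer(n_null),
                 null_k = as.integer(null_k), alpha = alpha,
                 seed = as.integer(seed)),
            class = "knockout_experiment")
}

# Centralities of the graph that survives removal of `remove`:
# by default restricted to the largest surviving component (nodes falling
# into smaller fragments get centrality 0 and are flagged disconnected);
# optionally computed per fragment.
survivor_centrality <- function(graph, remove, metrics = c("bc", "stress"),
                                fragment_mode = "largest_component") {
  keep <- setdiff(igraph::V(graph)$name, remove)
  g2 <- igraph::induced_subgraph(graph, keep)
  comp <- igraph::components(g2)
  main <- which.max(comp$csize)
  bc <- stats::setNames(numeric(length(keep)), igraph::V(g2)$name)
  st <- bc
  compute_on <- if (fragment_mode == "largest_component") main
                else seq_len(comp$no)
  for (k in compute_on) {
    members <- which(comp$membership == k)
    if (length(members) < 3) next  # no interior node on < 3 vertices
    sub <- igraph::induced_subgraph(g2, members)
    nm <- igraph::V(sub)$name
    if ("bc" %in% metrics) {
      bc[nm] <- igraph::betweenness(sub, directed = FALSE, normalized = FALSE)
    }
    if ("stress" %in% metrics) {
      el <- igraph::as_edgelist(sub, names = FALSE)
      st[nm] <- stress_brandes(length(nm), matrix(as.integer(el - 1L), ncol = 2))
    }
  }
  list(bc = bc, stress = st,
       disconnected = stats::setNames(comp$membership != main,
                                      igraph::V(g2)$name))
}

#' Simulate the knockout: centrality deltas for surviving nodes
#'
#' Removes the target nodes from the baseline, recomputes betweenness and
#' stress on the largest surviving component, and reports per-node deltas
#' (after minus before). Nodes disconnected from the main component by the
#' removal receive after-centrality 0 and are flagged. Targets themselves
#' are absent from the result.
#'
#' @param experiment a `knockout_experiment`.
#' @param fragment_mode `"largest_component"` (default) restricts the
#'   after-state to the largest surviving component; `"per_fragment"`
#'   recomputes centralities within every fragment.
#' @return A `perturbation_result` data frame with columns `node_id`,
#'   `bc_before`, `bc_after`, `stress_before`, `stress_after`, `delta_bc`,
#'   `delta_stress`, `disconnected`.
#' @export
knockout <- function(experiment,
                     fragment_mode = c("largest_component", "per_fragment")) {
  fragment_mode <- match.arg(fragment_mode)
  g <- experiment$baseline$graph
  before_bc <- betweenness_centrality(experiment$baseline)
  before_st <- stress_centrality(experiment$baseline)
  after <- survivor_centrality(g, experiment$targets_present,
                               fragment_mode = fragment_mode)
  ids <- sort(names(after$bc))
  res <- data.frame(
    node_id = ids,
    bc_before = as.numeric(before_bc[ids]),
    bc_after = as.numeric(after$bc[ids]),
    stress_before = as.numeric(before_st[ids]),
    stress_after = as.numeric(after$stress[ids]),
    stringsAsFactors = FALSE
  )
  res$delta_bc <- res$bc_after - res$bc_before
  res$delta_stress <- res$stress_after - res$stress_before
  res$disconnected <- as.logical(after$disconnected[ids])
  attr(res, "experiment") <- experiment[c("n_null", "null_k", "alpha", "seed")]
  attr(res, "fragment_mode") <- fragment_mode
  class(res) <- c("perturbation_result", "data.frame")
  res
}

#' Permutation null ensemble of betweenness changes
#'
#' Draws `n_null` random deletions of `null_k` nodes (uniform, without
#' replacement within a draw) from the baseline, recomputes betweenness on
#' the largest surviving component after each deletion, and records the
#' absolute per-node betweenness change. A node removed in a draw
#' contributes no sample for that draw (`NA`); the per-node count of
#' surviving draws is tracked for the p-value denominator.
#'
#' @param experiment a `knockout_experiment`; `seed` makes the ensemble
#'   reproducible.
#' @return A `null_ensemble`: list with `abs_delta` (nodes x draws numeric
#'   matrix of |delta BC|, `NA` where the node was deleted), and the draw
#'   metadata `n_null`, `k`, `seed`.
#' @export
null_distribution <- function(experiment) {
  g <- experiment$baseline$graph
  nodes <- igraph::V(g)$name
  k <- experiment$null_k
  if (k >= length(nodes)) stop("null_k must be smaller than the baseline size")
  before <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  mat <- matrix(NA_real_, nrow = length(nodes), ncol = experiment$n_null,
                dimnames = list(nodes, NULL))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(experiment$seed)
  for (b in seq_len(experiment$n_null)) {
    removed <- if (k > 0) sample(nodes, k) else character(0)
    after <- survivor_centrality(g, removed, metrics = "bc")
    ids <- names(after$bc)
    mat[ids, b] <- abs(after$bc - before[ids])
  }
  structure(list(abs_delta = mat, n_null = experiment$n_null, k = k,
                 seed = experiment$seed),
            class = "null_ensemble")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Empirical p-values against the permutation null
#'
#' For each surviving node v with B_v surviving null draws, the two-sided
#' empirical p-value of its observed betweenness change is
#' \deqn{p(v) = (1 + \#\{b : |\Delta_b(v)| \ge |\Delta_{obs}(v)|\}) / (B_v + 1)}
#' The +1 correction keeps p in (0, 1]. P-values are Benjamini-Hochberg
#' adjusted across all tested nodes and a node is flagged significant when
#' its adjusted p is at or below the experiment's alpha. A node with zero
#' surviving draws gets `NA` and is excluded from the BH family.
#'
#' @param result a `perturbation_result` from [knockout()].
#' @param ensemble a `null_ensemble` from [null_distribution()].
#' @param alpha significance threshold; defaults to the one stored on the
#'   result.
#' @param directional if `TRUE`, uses signed deltas (p for changes at least
#'   as extreme in the observed direction) instead of the default
#'   two-sided |delta| statistic.
#' @return The result with columns `n_null_surviving`, `p_bc`, `p_bc_adj`,
#'   `significant` appended.
#' @export
empirical_pvalues <- function(result, ensemble, alpha = NULL,
                              directional = FALSE) {
  if (is.null(alpha)) alpha <- attr(result, "experiment")$alpha
  if (is.null(alpha)) alpha <- 0.05
  missing <- setdiff(result$node_id, rownames(ensemble$abs_delta))
  if (length(missing)) {
    stop("ensemble does not cover node(s): ", paste(missing, collapse = ", "))
  }
  nulls <- ensemble$abs_delta[result$node_id, , drop = FALSE]
  obs <- if (directional) result$delta_bc else abs(result$delta_bc)
  p <- rep(NA_real_, nrow(result))
  B <- integer(nrow(result))
  for (i in seq_len(nrow(result))) {
    draws <- nulls[i, ]
    draws <- draws[!is.na(draws)]
    B[i] <- length(draws)
    if (B[i] == 0) next
    exceed <- if (directional && obs[i] < 0) sum(-draws <= obs[i])
              else sum(draws >= abs(obs[i]))
    p[i] <- (1 + exceed) / (B[i] + 1)
  }
  result$n_null_surviving <- B
  result$p_bc <- p
  result$p_bc_adj <- NA_real_
  tested <- !is.na(p)
  result$p_bc_adj[tested] <- stats::p.adjust(p[tested], method = "BH")
  result$significant <- result$p_bc_adj <= alpha
  result
}

#' Concordance between two knockout procedures
#'
#' Fraction of common nodes on which two perturbation results agree, per
#' metric. Two centrality-change values agree when equal within relative
#' tolerance `tol` (absolute tolerance `tol` near zero).
#'
#' @param result_a,result_b `perturbation_result` data frames.
#' @param tol relative agreement tolerance (default 1e-6).
#' @return List with `bc_overlap` and `stress_overlap`, each the agreeing
#'   fraction in `[0, 1]`, plus `n_common`.
#' @export
concordance <- function(result_a, result_b, tol = 1e-6) {
  common <- intersect(result_a$node_id, result_b$node_id)
  if (length(common) == 0) stop("no common node between the two results")
  ia <- match(common, result_a$node_id)
  ib <- match(common, result_b$node_id)
  agree <- function(x, y) {
    scale <- pmax(abs(x), abs(y), 1)
    abs(x - y) <= tol * scale
  }
  list(
    bc_overlap = mean(agree(result_a$delta_bc[ia], result_b$delta_bc[ib])),
    stress_overlap = mean(agree(result_a$delta_stress[ia],
                                result_b$delta_stress[ib])),
    n_common = length(common)
  )
}

#' Write a perturbation result as TSV
#'
#' @param result a `perturbation_result`.
#' @param path output path.
#' @param digits significant digits for numeric columns (fixed precision
#'   keeps reruns diffable).
#' @return `path`, invisibly.
#' @export
write_perturbation_tsv <- function(result, path, digits = 10) {
  out <- as.data.frame(result)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.*g", digits, x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
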