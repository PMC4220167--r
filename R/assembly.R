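#' The fixed subset-to-district map
#'
#' The molecular catalog is assembled from 13 data sources (one of which,
#' the literature-review pathway expansion, contributes sub-subsets 3A--3E,
#' and the expression source splits into down-/up-regulated halves 9A/9B).
#' Each subset ID maps to one of 8 biochemical districts: Genomic,
#' Epigenomic, Transcriptomic, Post-transcriptomic, Proteomic, Microbiome,
#' Inflammation, Others (growth and differentiation).
#'
#' @return Named character vector: subset ID -> district label.
#' @export
district_map <- function() {
  c("1"  = "Genomic",
    "4"  = "Epigenomic",
    "7"  = "Transcriptomic", "9A" = "Transcriptomic", "9B" = "Transcriptomic",
    "8"  = "Post-transcriptomic",
    "2"  = "Proteomic",
    "5"  = "Microbiome", "10" = "Microbiome", "12" = "Microbiome",
    "13" = "Microbiome",
    "6"  = "Inflammation", "3A" = "Inflammation", "3B" = "Inflammation",
    "3C" = "Inflammation",
    "3"  = "Others", "11" = "Others", "3D" = "Others", "3E" = "Others")
}

#' @rdname district_map
#' @export
district_labels <- function() {
  unique(unname(district_map()))
}

#' Merge molecular subsets into a node catalog
#'
#' Takes the union of overlapping molecule subsets and annotates every
#' molecule with all subsets containing it plus the districts those subsets
#' induce. The merge is idempotent and order-independent: a permutation of
#' the same subsets yields an identical catalog.
#'
#' @param subsets named list of character vectors; names are subset IDs and
#'   must appear in `dmap`. Blank or missing member IDs are rejected.
#' @param dmap subset-to-district map, by default [district_map()].
#' @return A `node_catalog` data frame with columns `node_id`, `subsets`
#'   (semicolon-separated sorted subset IDs) and `districts`
#'   (semicolon-separated sorted district labels), ordered by `node_id`.
#' @examples
#' cat3 <- merge_subsets(list("1" = c("A", "B"), "2" = c("B", "C")))
#' nrow(cat3) # 3; B carries both memberships
#' @export
merge_subsets <- function(subsets, dmap = district_map()) {
  if (is.null(names(subsets)) || anyDuplicated(names(subsets))) {
    stop("subsets must be a uniquely named list of member vectors")
  }
  unknown <- setdiff(names(subsets), names(dmap))
  if (length(unknown)) {
    stop("unknown subset id(s) not in district map: ",
         paste(unknown, collapse = ", "))
  }
  for (id in names(subsets)) {
    m <- subsets[[id]]
    if (length(m) == 0) stop("subset ", id, " is empty")
    if (any(is.na(m) | !nzchar(trimws(m)))) stop("blank member ID in subset ", id)
  }
  long <- data.frame(
    node_id = unlist(subsets, use.names = FALSE),
    subset_id = rep(names(subsets), lengths(subsets)),
    stringsAsFactors = FALSE
  )
  memb <- lapply(split(long$subset_id, long$node_id), function(s) sort(unique(s)))
  ids <- sort(names(memb))
  catalog <- data.frame(
    node_id = ids,
    subsets = vapply(memb[ids], paste, character(1), collapse = ";"),
    districts = vapply(memb[ids], function(s) {
      paste(sort(unique(unname(dmap[s]))), collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  class(catalog) <- c("node_catalog", "data.frame")
  catalog
}

#' Districts of catalogued molecules
#'
#' @param catalog a `node_catalog`.
#' @param node_ids molecules to look up; default all.
#' @return Named list of character vectors of district labels.
#' @export
catalog_districts <- function(catalog, node_ids = catalog$node_id) {
  idx <- match(node_ids, catalog$node_id)
  if (anyNA(idx)) stop("node(s) not in catalog: ",
                       paste(node_ids[is.na(idx)], collapse = ", "))
  stats::setNames(strsplit(catalog$districts[idx], ";", fixed = TRUE), node_ids)
}

#' Collapse multiple probes per gene to the most variable probe
#'
#' Microarray platforms measure many genes with several probes. For each
#' gene the probe with the highest standard deviation across all samples
#' (both groups pooled, sample SD with n-1 denominator) is retained to
#' represent the gene; ties are broken by the lexicographically smallest
#' probe ID so the result is deterministic.
#'
#' @param expr expression data frame: columns `probe_id`, `gene_id`, then
#'   one numeric column per sample (log2 scale).
#' @return The same data frame restricted to one row per gene.
#' @export
collapse_probes <- function(expr) {
  check_expression(expr)
  vals <- as.matrix(expr[, sample_columns(expr), drop = FALSE])
  sds <- apply(vals, 1, stats::sd)
  ord <- order(expr$gene_id, -sds, expr$probe_id)
  expr <- expr[ord, , drop = FALSE]
  out <- expr[!duplicated(expr$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

sample_columns <- function(expr) {
  setdiff(colnames(expr), c("probe_id", "gene_id"))
}

check_expression <- function(expr) {
  if (!all(c("probe_id", "gene_id") %in% colnames(expr))) {
    stop("expression table needs probe_id and gene_id columns")
  }
  if (any(!nzchar(expr$gene_id) | is.na(expr$gene_id))) stop("blank gene_id")
  if (length(sample_columns(expr)) < 2) stop("need at least 2 sample columns")
  invisible(TRUE)
}

#' Fold-change filter for differential expression
#'
#' Flags genes whose mean log2 expression differs between two sample groups
#' by at least `log2(fc_threshold)`: a gene is up-regulated when
#' `mean(group_b) - mean(group_a) >= log2(fc_threshold)` and down-regulated
#' when the difference is `<= -log2(fc_threshold)` (threshold inclusive).
#' Values are assumed already log2-normalized, so a fold-change of 2
#' corresponds to an absolute log2 difference of 1. Probes should be
#' collapsed first ([collapse_probes()]).
#'
#' @param expr collapsed expression data frame (one row per gene).
#' @param group_a,group_b non-empty character vectors of sample column
#'   names; `group_a` is the reference (e.g. healthy controls).
#' @param fc_threshold linear-scale fold-change threshold, default 2.
#' @return List with character vectors `up` and `down` (disjoint gene sets)
#'   and the numeric vector `log2fc` named by gene.
#' @export
fold_change_filter <- function(expr, group_a, group_b, fc_threshold = 2) {
  check_expression(expr)
  if (length(group_a) == 0 || length(group_b) == 0) stop("empty sample group")
  missing <- setdiff(c(group_a, group_b), sample_columns(expr))
  if (length(missing)) stop("unknown sample(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(expr$gene_id)) {
    stop("duplicate gene_id: collapse probes before filtering")
  }
  a <- rowMeans(expr[, group_a, drop = FALSE])
  b <- rowMeans(expr[, group_b, drop = FALSE])
  lfc <- stats::setNames(b - a, expr$gene_id)
  cut <- log2(fc_threshold)
  list(up = sort(names(lfc)[lfc >= cut]),
       down = sort(names(lfc)[lfc <= -cut]),
       log2fc = lfc)
}

#' Hypergeometric over-representation analysis
#'
#' For each pathway, tests whether the gene list contains more pathway
#' members than expected under random draws from the universe. With
#' universe size N, pathway size K (after intersecting with the universe),
#' list size n and k observed hits, the p-value is the upper hypergeometric
#' tail \eqn{P(X \ge k)} (inclusive). P-values are Benjamini-Hochberg
#' adjusted across all tested pathways.
#'
#' @param gene_list character vector of genes; must be a subset of
#'   `universe`.
#' @param pathways named list of character vectors (pathway members).
#' @param universe character vector defining the background population.
#' @return Data frame with one row per pathway (`pathway_id`, `k`, `K`,
#'   `n`, `N`, `p`, `p_adj`), sorted by increasing `p` then pathway ID.
#' @examples
#' ora <- hypergeometric_ora(letters[1:5],
#'   pathways = list(P = letters[1:5]), universe = letters[1:10])
#' ora$p # choose(5,5)/choose(10,5) = 1/252
#' @export
hypergeometric_ora <- function(gene_list, pathways, universe) {
  gene_list <- unique(gene_list)
  universe <- unique(universe)
  if (!all(gene_list %in% universe)) {
    stop("gene_list contains genes outside the universe")
  }
  if (is.null(names(pathways)) || anyDuplicated(names(pathways))) {
    stop("pathways must be a uniquely named list")
  }
  N <- length(universe)
  n <- length(gene_list)
  rows <- lapply(names(pathways), function(pid) {
    pw <- intersect(unique(pathways[[pid]]), universe)
    if (length(pw) == 0) stop("pathway ", pid, " has no member in the universe")
    K <- length(pw)
    k <- length(intersect(gene_list, pw))
    # upper tail P(X >= k), inclusive
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = pid, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$pathway_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read molecular subset and pathway files
#'
#' `read_subset_tsv()` reads one molecule ID per line (an optional second
#' tab-separated annotation column is ignored). `read_gmt()` reads
#' GMT-style pathway files: `pathway<TAB>description<TAB>member...`.
#'
#' @param path file path.
#' @return `read_subset_tsv()`: character vector of IDs. `read_gmt()`:
#'   named list of member vectors.
#' @export
read_subset_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  ids <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1)
  ids <- trimws(ids)
  if (any(!nzchar(ids))) stop("blank molecule ID in ", path)
  unique(ids)
}

#' @rdname read_subset_tsv
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop(sprintf("malformed GMT row at line %d", i))
    out[[f[1]]] <- unique(f[3:length(f)])
  }
  out
}

#' Write a node catalog as TSV
#'
#' @param catalog a `node_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog_tsv <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog_tsv
#' @param path catalog TSV written by [write_catalog_tsv()].
#' @export
read_catalog_tsv <- function(path) {
  catalog <- utils::read.table(path, sep = "\t", header = TRUE,
                               colClasses = "character")
  class(catalog) <- c("node_catalog", "data.frame")
  catalog
}
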