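test_that("merge_subsets unions members and accumulates memberships", {
  catalog <- merge_subsets(list("1" = c("A", "B"), "2" = c("B", "C")))
  expect_equal(nrow(catalog), 3)
  expect_equal(catalog$subsets[catalog$node_id == "B"], "1;2")
  expect_equal(catalog$districts[catalog$node_id == "B"], "Genomic;Proteomic")

  one <- merge_subsets(list("1" = "A"))
  expect_equal(nrow(one), 1)

  expect_error(merge_subsets(list(ZZ = "A")), "unknown subset")
  expect_error(merge_subsets(list("1" = c("A", ""))), "blank")
})

test_that("merge is idempotent and order-independent", {
  subs <- list("1" = c("A", "B", "C"), "2" = c("B", "D"), "5" = c("A", "E"))
  expect_identical(merge_subsets(subs), merge_subsets(rev(subs)))
})

test_that("six overlapping subsets with sizes summing to 432 union to 377", {
  # subset i reuses overlap_i members of subset i-1; 55 reused IDs in
  # total, so sizes sum to 432 while the union holds 377 molecules
  ids <- sprintf("m%03d", 1:377)
  sizes <- c(100, 90, 80, 70, 60, 32) # sums to 432
  canonical <- c("1", "2", "3", "4", "5", "6")
  overlaps <- c(0, 11, 11, 11, 11, 11) # total duplicated = 55 = 432 - 377
  subs <- list()
  cursor <- 0
  prev <- character(0)
  for (i in seq_along(sizes)) {
    reuse <- if (overlaps[i] > 0) prev[seq_len(overlaps[i])] else character(0)
    fresh_n <- sizes[i] - length(reuse)
    fresh <- ids[cursor + seq_len(fresh_n)]
    cursor <- cursor + fresh_n
    subs[[canonical[i]]] <- c(reuse, fresh)
    prev <- subs[[canonical[i]]]
  }
  expect_equal(sum(lengths(subs)), 432)
  expect_equal(nrow(merge_subsets(subs)), 377)
})

test_that("district map is total over the catalog subset IDs with 8 districts", {
  dm <- district_map()
  expect_length(district_labels(), 8)
  expect_setequal(names(dm),
                  c("1", "2", "3", "4", "5", "6", "7", "8", "9A", "9B",
                    "10", "11", "12", "13", "3A", "3B", "3C", "3D", "3E"))
  expect_equal(unname(dm[c("5", "10", "12", "13")]), rep("Microbiome", 4))
})

make_expr <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(probe_id = r[[1]], gene_id = r[[2]],
               s1 = r[[3]][1], s2 = r[[3]][2], s3 = r[[3]][3], s4 = r[[3]][4],
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

test_that("probe collapse keeps the highest-SD probe, smallest ID on ties", {
  expr <- make_expr(list(
    list("p2", "G1", c(5, 5.5, 5, 5.5)),     # sd ~0.29
    list("p1", "G1", c(4, 6, 4, 6)),          # sd ~1.15 -> retained
    list("p3", "G2", c(7, 7, 7, 7))           # single probe, unchanged
  ))
  out <- collapse_probes(expr)
  expect_equal(sort(out$probe_id), c("p1", "p3"))

  tie <- make_expr(list(
    list("pB", "G1", c(1, 2, 1, 2)),
    list("pA", "G1", c(2, 3, 2, 3))           # same SD, smaller ID wins
  ))
  expect_equal(collapse_probes(tie)$probe_id, "pA")
})

test_that("fold-change filter applies the inclusive log2 threshold per direction", {
  expr <- make_expr(list(
    list("p1", "UP",   c(5.0, 5.0, 6.2, 6.2)),  # log2FC 1.2 -> up
    list("p2", "DOWN", c(5.0, 5.0, 4.0, 4.0)),  # log2FC -1 -> down (inclusive)
    list("p3", "FLAT", c(5.0, 5.0, 5.5, 5.5))   # 0.5 -> excluded
  ))
  de <- fold_change_filter(expr, c("s1", "s2"), c("s3", "s4"))
  expect_equal(de$up, "UP")
  expect_equal(de$down, "DOWN")
  expect_length(intersect(de$up, de$down), 0)
  expect_error(fold_change_filter(expr, character(0), c("s3", "s4")), "empty")
})

test_that("raising the fold-change threshold never adds genes", {
  set.seed(8)
  expr <- data.frame(probe_id = sprintf("p%02d", 1:30),
                     gene_id = sprintf("g%02d", 1:30),
                     s1 = rnorm(30, 7), s2 = rnorm(30, 7),
                     s3 = rnorm(30, 7, 2), s4 = rnorm(30, 7, 2),
                     stringsAsFactors = FALSE)
  loose <- fold_change_filter(expr, c("s1", "s2"), c("s3", "s4"), 1.5)
  tight <- fold_change_filter(expr, c("s1", "s2"), c("s3", "s4"), 2.5)
  expect_true(all(tight$up %in% loose$up))
  expect_true(all(tight$down %in% loose$down))
  expect_lte(length(loose$up) + length(loose$down), 30)
})

test_that("hypergeometric p-values equal exact combinatorial enumeration", {
  # k=5 of 5 drawn from a pathway of 5 in a universe of 10
  ora <- hypergeometric_ora(letters[1:5], list(P = letters[1:5]), letters[1:10])
  expect_equal(ora$p, 1 / choose(10, 5), tolerance = 1e-12)

  # zero hits: P(X >= 0) = 1
  ora0 <- hypergeometric_ora(letters[6:8], list(P = letters[1:3]), letters[1:10])
  expect_equal(ora0$k, 0)
  expect_equal(ora0$p, 1)

  # exact enumeration over a dense grid, N <= 50
  enum_tail <- function(k, K, N, n) {
    kk <- k:min(K, n)
    sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
  }
  for (N in c(5, 12, 27, 50)) {
    universe <- sprintf("u%02d", 1:N)
    for (K in unique(c(1, 2, N %/% 2, N))) {
      for (n in unique(c(1, N %/% 3, N %/% 2))) {
        if (n < 1) next
        pw <- universe[1:K]
        gl <- universe[seq(N, N - n + 1)]
        k <- length(intersect(gl, pw))
        got <- hypergeometric_ora(gl, list(P = pw), universe)$p
        expect_equal(got, enum_tail(k, K, N, n), tolerance = 1e-12)
      }
    }
  }
})

test_that("BH adjustment matches the step-up formula and orders consistently", {
  # two pathways with raw p 0.01 and 0.04 -> adjusted 0.02 and 0.04
  expect_equal(p.adjust(c(0.01, 0.04), "BH"), c(0.02, 0.04))
  set.seed(4)
  p <- runif(25)^2
  expect_equal(p.adjust(p, "BH"), bh_stepup(p), tolerance = 1e-12)

  universe <- sprintf("u%02d", 1:40)
  ora <- hypergeometric_ora(universe[1:10],
                            list(A = universe[1:12], B = universe[5:30],
                                 C = universe[30:40]),
                            universe)
  expect_true(all(diff(ora$p) >= 0))          # sorted by p
  expect_true(all(ora$p_adj >= ora$p - 1e-15))
  expect_true(all(ora$p_adj <= 1))
  expect_true(all(ora$k <= pmin(ora$K, ora$n)))
})

test_that("ORA rejects gene lists outside the universe", {
  expect_error(hypergeometric_ora(c("a", "zz"), list(P = c("a", "b")),
                                  letters[1:5]),
               "outside the universe")
})

test_that("subset and GMT readers handle annotations and malformed rows", {
  sp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tsome note", "B", "", "C"), sp)
  expect_equal(read_subset_tsv(sp), c("A", "B", "C"))

  gp <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("pw1\tdesc\tA\tB", "pw2\tdesc\tC"), gp)
  gmt <- read_gmt(gp)
  expect_equal(gmt$pw1, c("A", "B"))
  writeLines("broken\tdesc", gp)
  expect_error(read_gmt(gp), "line 1")
})

test_that("catalogs round-trip through TSV", {
  catalog <- merge_subsets(list("1" = c("A", "B"), "4" = "B"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog_tsv(catalog, path)
  expect_identical(read_catalog_tsv(path), catalog)
})
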