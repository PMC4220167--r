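test_that("knockout on a path: survivors of the cut have zero deltas and flags", {
  p3 <- path_network(c("A", "B", "C"))
  exp <- knockout_experiment(p3, "B", n_null = 2, seed = 1)
  res <- knockout(exp)
  expect_setequal(res$node_id, c("A", "C"))
  expect_equal(res$delta_bc, c(0, 0))
  # one endpoint keeps the 1-node "largest" component, the other is flagged
  expect_equal(sum(res$disconnected), 1)
})

test_that("removing a star leaf follows the closed form", {
  n <- 8 # leaves
  st <- star_network(n)
  exp <- knockout_experiment(st, "leaf01", n_null = 1, seed = 1)
  res <- knockout(exp)
  hub <- res[res$node_id == "hub", ]
  expect_equal(hub$bc_before, n * (n - 1) / 2)
  expect_equal(hub$bc_after, (n - 1) * (n - 2) / 2)
  expect_equal(hub$delta_bc, (n - 1) * (n - 2) / 2 - n * (n - 1) / 2)
})

test_that("knockout deltas equal brute-force recomputation on the edited graph", {
  for (seed in c(5, 6, 7)) {
    nw <- random_connected_network(30, p = 0.18, seed = seed)
    set.seed(seed + 100)
    targets <- sample(network_nodes(nw), 3)
    exp <- knockout_experiment(nw, targets, n_null = 1, seed = seed)
    res <- knockout(exp)

    before <- oracle_centralities(nw)
    kept <- setdiff(network_nodes(nw), targets)
    sub <- igraph::induced_subgraph(nw$graph, kept)
    comp <- igraph::components(sub)
    main_ids <- igraph::V(sub)$name[comp$membership == which.max(comp$csize)]
    edited <- structure(list(graph = igraph::induced_subgraph(sub, main_ids),
                             name = "", provenance = ""),
                        class = "interaction_network")
    after <- oracle_centralities(edited)
    for (i in seq_len(nrow(res))) {
      id <- res$node_id[i]
      exp_after_bc <- if (id %in% main_ids) after$bc[[id]] else 0
      exp_after_st <- if (id %in% main_ids) after$stress[[id]] else 0
      expect_equal(res$delta_bc[i], exp_after_bc - before$bc[[id]],
                   tolerance = 1e-9)
      expect_equal(res$delta_stress[i], exp_after_st - before$stress[[id]],
                   tolerance = 1e-9)
    }
  }
})

test_that("knockout rejects target sets covering the baseline", {
  p3 <- path_network(c("A", "B", "C"))
  expect_error(knockout_experiment(p3, c("A", "B", "C")), "cover")
  expect_error(knockout_experiment(p3, "Z"), "no target")
})

test_that("null ensembles are seed-reproducible and track removed nodes", {
  nw <- random_connected_network(40, p = 0.15, seed = 9)
  exp <- knockout_experiment(nw, network_nodes(nw)[1:4], n_null = 5, seed = 42)
  e1 <- null_distribution(exp)
  e2 <- null_distribution(exp)
  expect_identical(e1$abs_delta, e2$abs_delta)
  expect_equal(dim(e1$abs_delta), c(40, 5))
  # each draw removes exactly k nodes
  expect_equal(unname(colSums(is.na(e1$abs_delta))), rep(4, 5))
  expect_true(all(e1$abs_delta >= 0, na.rm = TRUE))
  expect_true(any(e1$abs_delta > 0, na.rm = TRUE))
})

test_that("k = 0 null draws produce exactly zero deltas", {
  nw <- random_connected_network(20, p = 0.25, seed = 10)
  exp <- knockout_experiment(nw, network_nodes(nw)[1], n_null = 3,
                             null_k = 0, seed = 1)
  ens <- null_distribution(exp)
  expect_true(all(ens$abs_delta == 0))
})

test_that("empirical p-values follow the +1/(B+1) estimator and BH", {
  nw <- random_connected_network(25, p = 0.2, seed = 12)
  exp <- knockout_experiment(nw, network_nodes(nw)[1:3], n_null = 19, seed = 3)
  res <- empirical_pvalues(knockout(exp), null_distribution(exp))
  expect_true(all(res$p_bc > 0 & res$p_bc <= 1, na.rm = TRUE))
  # verify the formula on every node against the stored ensemble
  ens <- null_distribution(exp)
  for (i in seq_len(nrow(res))) {
    draws <- ens$abs_delta[res$node_id[i], ]
    draws <- draws[!is.na(draws)]
    expect_equal(res$p_bc[i],
                 (1 + sum(draws >= abs(res$delta_bc[i]))) / (length(draws) + 1))
  }
  tested <- !is.na(res$p_bc)
  expect_equal(res$p_bc_adj[tested], bh_stepup(res$p_bc[tested]),
               tolerance = 1e-12)
  # an observed delta of 0 can never beat the null
  zero <- which(res$delta_bc == 0)
  expect_true(all(res$p_bc[zero] == 1))
  # BH never declares more than uncorrected testing
  alpha <- attr(res, "experiment")$alpha
  expect_lte(sum(res$p_bc_adj <= alpha, na.rm = TRUE),
             sum(res$p_bc <= alpha, na.rm = TRUE))
})

test_that("a delta exceeding every null draw gets p = 1/(B+1)", {
  # estimator floor: B surviving draws, all smaller than the observation
  nw <- random_connected_network(30, p = 0.2, seed = 13)
  exp <- knockout_experiment(nw, network_nodes(nw)[1:2], n_null = 9, seed = 5)
  res <- knockout(exp)
  ens <- null_distribution(exp)
  res$delta_bc[1] <- max(ens$abs_delta, na.rm = TRUE) + 1
  out <- empirical_pvalues(res, ens)
  B <- out$n_null_surviving[1]
  expect_equal(out$p_bc[1], 1 / (B + 1))
})

test_that("concordance counts agreeing common nodes per metric", {
  nw <- random_connected_network(40, p = 0.12, seed = 14)
  exp <- knockout_experiment(nw, network_nodes(nw)[1:4], n_null = 1, seed = 1)
  a <- knockout(exp)
  expect_equal(concordance(a, a), list(bc_overlap = 1, stress_overlap = 1,
                                       n_common = nrow(a)))
  b <- a
  b$delta_bc[1] <- b$delta_bc[1] + 10
  expect_equal(concordance(a, b)$bc_overlap, (nrow(a) - 1) / nrow(a))
  expect_equal(concordance(a, b)$stress_overlap, 1)

  # largest-component vs per-fragment procedures agree unless the
  # removal fragments the graph
  frag <- knockout(exp, "per_fragment")
  ov <- concordance(a, frag)
  expect_lte(ov$bc_overlap, 1)
  if (!any(a$disconnected)) expect_equal(ov$bc_overlap, 1)
  expect_error(concordance(a[0, ], a[0, ]), "no common node")
})

test_that("pendant-leaf removal on a tree leaves other deltas at zero", {
  # star with a pendant path: removing the far leaf only shortens its pairs
  nw <- interaction_network(rbind(c("hub", "a"), c("hub", "b"), c("hub", "c"),
                                  c("c", "d")))
  exp <- knockout_experiment(nw, "d", n_null = 1, seed = 1)
  res <- knockout(exp)
  # deltas of a and b are zero; hub and c lose only pairs involving d
  expect_equal(res$delta_bc[res$node_id %in% c("a", "b")], c(0, 0))
  expect_equal(res$delta_bc[res$node_id == "c"], -3) # d paired with hub,a,b
})

test_that("the significant set is reproducible end to end", {
  nw <- random_connected_network(60, p = 0.1, seed = 20)
  run <- function() {
    exp <- knockout_experiment(nw, network_nodes(nw)[1:5], n_null = 30,
                               seed = 77)
    res <- empirical_pvalues(knockout(exp), null_distribution(exp))
    res$node_id[which(res$significant)]
  }
  expect_identical(run(), run())
})
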