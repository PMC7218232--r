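path_graph <- function(cost_ab = 0.4) {
  igraph::graph_from_data_frame(
    data.frame(from = "a", to = "b", cost = cost_ab), directed = FALSE)
}

test_that("terminal selection caps, filters and normalises prizes", {
  n <- 500
  W <- matrix(0, n, 1)
  W[, 1] <- stats::rexp(n) + 5  # everything qualifies (low spread)
  W[1, 1] <- max(W) # known top
  rownames(W) <- sprintf("mRNA_%04d", 1:n)
  fake <- structure(list(Z = matrix(0, 3, 1), W = list(mRNA = W)),
                    class = "factor_model")
  nm <- data.table::data.table(feature_id = rownames(W), modality = "mRNA",
                               node_id = sprintf("Gene%04d", 1:n))
  # with a tiny fold requirement all 500 qualify; cap keeps 200
  out <- suppressMessages(select_terminals(fake, 1, nm, fold = 0.1))
  expect_equal(nrow(out), 200)
  expect_equal(max(out$prize), 1)
  expect_true(sprintf("Gene%04d", 1) %in% out$node_id)
  # uniform weights: expectation equals the value, 2x is unattainable
  W2 <- matrix(1, 50, 1, dimnames = list(sprintf("mRNA_%04d", 1:50), NULL))
  fake2 <- structure(list(Z = matrix(0, 3, 1), W = list(mRNA = W2)),
                     class = "factor_model")
  out2 <- select_terminals(fake2, 1, nm[1:50])
  expect_equal(nrow(out2), 0)
  # single loaded feature keeps prize 1
  W3 <- matrix(0, 50, 1, dimnames = list(sprintf("mRNA_%04d", 1:50), NULL))
  W3[7, 1] <- 2
  fake3 <- structure(list(Z = matrix(0, 3, 1), W = list(mRNA = W3)),
                     class = "factor_model")
  out3 <- select_terminals(fake3, 1, nm[1:50])
  expect_equal(out3$feature_id, "mRNA_0007")
  expect_equal(out3$prize, 1)
  expect_error(select_terminals(fake3, 5, nm), "out of range")
})

test_that("a two-node path splits or joins depending on the tree cost", {
  tt <- data.table::data.table(node_id = c("a", "b"), prize = c(1, 1))
  s1 <- solve_pcsf(path_graph(), tt, pcsf_config(mu = 0, omega = 0.6,
                                                 beta = 1))
  expect_equal(s1$n_trees, 1)
  expect_equal(nrow(s1$edges), 1)
  expect_equal(s1$objective, 0.4 + 0.6 - 2)
  s2 <- solve_pcsf(path_graph(), tt, pcsf_config(mu = 0, omega = 0.2,
                                                 beta = 1))
  expect_equal(s2$n_trees, 2)
  expect_equal(nrow(s2$edges), 0)
  s3 <- solve_pcsf(path_graph(), tt, pcsf_config(mu = 0, omega = 0.6,
                                                 beta = 0))
  expect_equal(length(s3$nodes), 0)
})

test_that("the heuristic matches the exhaustive oracle on small instances", {
  n_exact <- 0
  for (i in 1:50) {
    inst <- random_pcsf_instance(2000 + i)
    ex <- solve_pcsf(inst$net, inst$terminals, inst$config)
    gw <- solve_pcsf(inst$net, inst$terminals, inst$config,
                     force_heuristic = TRUE)
    gap <- gw$objective - ex$objective
    expect_lte(gap, 0.05 * abs(ex$objective) + 1e-9)
    if (gap < 1e-9) n_exact <- n_exact + 1
    # objective decomposition holds for both solvers
    expect_equal(ex$objective, pcsf_objective(ex), tolerance = 1e-9)
    expect_equal(gw$objective, pcsf_objective(gw), tolerance = 1e-9)
  }
  expect_gte(n_exact, 45)
})

test_that("solutions are forests whose trees all carry prize", {
  for (i in 1:10) {
    inst <- random_pcsf_instance(3000 + i)
    sol <- solve_pcsf(inst$net, inst$terminals, inst$config,
                      force_heuristic = TRUE)
    if (length(sol$nodes) == 0) next
    # forest: edges = nodes - trees
    expect_equal(nrow(sol$edges), length(sol$nodes) - sol$n_trees)
    for (tr in unique(sol$tree_id)) {
      members <- names(sol$tree_id)[sol$tree_id == tr]
      expect_gt(sum(sol$prize_included[match(members, sol$nodes)]), 0)
    }
  }
})

test_that("unreachable terminals yield an empty forest with status", {
  g <- path_graph()
  tt <- data.table::data.table(node_id = "zz", prize = 1)
  sol <- solve_pcsf(g, tt, pcsf_config())
  expect_equal(sol$status, "no-terminal")
  expect_equal(length(sol$nodes), 0)
})

test_that("grid search picks the smallest beta once coverage saturates", {
  # six isolated high-prize terminals: coverage is 100% at every grid point
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, 6, name = paste0("t", 1:6))
  tt <- data.table::data.table(node_id = paste0("t", 1:6), prize = 1)
  gs <- grid_search(g, tt)
  expect_equal(gs$chosen$beta, 100)
  expect_equal(gs$chosen$omega, 0.2)
  expect_true(all(gs$curve$coverage == 100))
  expect_true(all(gs$curve$n_trees == 6))
})

test_that("optimal coverage is monotone in the prize scale", {
  for (i in 1:10) {
    inst <- random_pcsf_instance(4000 + i)
    covs <- vapply(c(0.2, 0.5, 1, 2, 4), function(be) {
      cfg <- inst$config; cfg$beta <- be
      solve_pcsf(inst$net, inst$terminals, cfg)$coverage
    }, 0)
    expect_true(all(diff(covs) >= -1e-9))
  }
})

test_that("the ensemble with r = 0 reduces to the single run", {
  inst <- random_pcsf_instance(77)
  cfg <- inst$config; cfg$r <- 0; cfg$runs <- 4
  single <- solve_pcsf(inst$net, inst$terminals, cfg)
  ens <- ensemble_solve(inst$net, inst$terminals, cfg)
  expect_setequal(igraph::V(ens)$name, single$nodes)
  if (igraph::ecount(ens) > 0) {
    expect_true(all(igraph::E(ens)$frequency == 1))
  }
  # with noise, frequencies live on the {1..runs}/runs grid and the union
  # contains any single run
  cfg2 <- inst$config; cfg2$r <- 0.3; cfg2$runs <- 5
  ens2 <- ensemble_solve(inst$net, inst$terminals, cfg2)
  if (igraph::ecount(ens2) > 0) {
    expect_true(all(igraph::E(ens2)$frequency %in% (1:5) / 5))
  }
  set.seed(cfg2$seed + 1)
  noise <- 1 + stats::runif(igraph::ecount(inst$net), -0.3, 0.3)
  run1 <- solve_pcsf(inst$net, inst$terminals, cfg2,
                     cost = igraph::E(inst$net)$cost * noise)
  expect_true(all(run1$nodes %in% igraph::V(ens2)$name))
})

test_that("edge-betweenness clustering splits two bridged triangles", {
  ed <- data.frame(
    from = c("a1", "a2", "a3", "b1", "b2", "b3", "a1"),
    to   = c("a2", "a3", "a1", "b2", "b3", "b1", "b1"),
    cost = 0.2)
  g <- igraph::graph_from_data_frame(ed[!duplicated(ed[1:2]), ],
                                     directed = FALSE)
  cl <- cluster_network(g)
  expect_equal(length(unique(cl$membership)), 2)
  expect_equal(cl$membership[["a1"]], cl$membership[["a2"]])
  expect_false(cl$membership[["a1"]] == cl$membership[["b1"]])
  # complete graph stays one cluster
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- paste0("k", 1:4)
  igraph::E(k4)$cost <- 0.2
  expect_equal(length(unique(cluster_network(k4)$membership)), 1)
  # disconnected components are never merged
  g2 <- igraph::disjoint_union(g, k4)
  cl2 <- cluster_network(g2)
  expect_false(cl2$membership[["a1"]] == cl2$membership[["k1"]])
})

test_that("cluster profiles summarise fold changes and significance", {
  membership <- c(Gene0001 = 1L, Gene0002 = 1L, Met0001 = 2L)
  nm <- data.table::data.table(
    feature_id = c("mRNA_0001", "mRNA_0002", "Met0001"),
    modality = c("mRNA", "mRNA", "metabolite"),
    node_id = c("Gene0001", "Gene0002", "Met0001"))
  ct <- data.table::data.table(
    feature_id = c("mRNA_0001", "mRNA_0002"), logFC = c(1, 1),
    significant = c(FALSE, FALSE))
  data.table::setattr(ct, "contrast",
                      list(modality = "mRNA", group = "3R4F", timepoint = 6))
  tabs <- list(mRNA = list("3R4F@6" = ct))
  prof <- cluster_profiles(membership, tabs, nm)
  r <- prof[cluster == 1 & group == "3R4F"]
  expect_equal(r$mean_logfc, 1)
  expect_equal(r$pct_significant, 0)
  # cluster 2 has no measured molecule -> null row
  expect_true(any(prof$cluster == 2 & is.na(prof$mean_logfc)))
})

test_that("factor-1 clusters separate smoke from heated-tobacco contrasts", {
  st <- fx_study()
  layers <- fx_layers()
  tabs <- fit_all_contrasts(layers["mRNA"], st$sheet,
                            groups = c("3R4F", "CHTP"), timepoints = 6)
  terms <- suppressMessages(select_terminals(fx_model(), 1, fx_node_map()))
  cfg <- pcsf_config()
  ens <- ensemble_solve(fx_network(), terms, cfg)
  cl <- cluster_network(ens)
  prof <- cluster_profiles(cl$membership, tabs, fx_node_map())
  agg <- prof[!is.na(group),
              .(pct = mean(pct_significant)), by = group]
  expect_gt(agg[group == "3R4F"]$pct, agg[group == "CHTP"]$pct)
})
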