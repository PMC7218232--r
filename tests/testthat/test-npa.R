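tiny_net <- function() {
  causal_network(
    nodes = c("A", "B"),
    edges = data.table::data.table(from = "A", to = "B", sign = 1,
                                   weight = 1),
    downstream = list(
      A = data.table::data.table(gene = c("g1", "g2"), sign = c(1, -1)),
      B = data.table::data.table(gene = c("g3", "g4"), sign = c(1, 1))))
}

gene_map4 <- data.table::data.table(feature_id = paste0("f", 1:4),
                                    gene = paste0("g", 1:4))

ct_of <- function(lfc) {
  data.table::data.table(feature_id = paste0("f", 1:4), logFC = lfc)
}

test_that("backbone differentials average signed downstream fold changes", {
  f <- backbone_differentials(tiny_net(), ct_of(c(1, -1, 0, 0)), gene_map4)
  expect_equal(unname(f["A"]), 1)  # (1*1 + (-1)*(-1)) / 2
  expect_equal(unname(f["B"]), 0)
  # all-zero fold changes
  f0 <- backbone_differentials(tiny_net(), ct_of(rep(0, 4)), gene_map4)
  expect_equal(unname(f0), c(0, 0))
  # flipping every downstream sign negates f
  net2 <- tiny_net()
  net2$downstream <- lapply(net2$downstream, function(d) {
    d$sign <- -d$sign; d
  })
  f2 <- backbone_differentials(net2, ct_of(c(1, -1, 0.5, 0.2)), gene_map4)
  f1 <- backbone_differentials(tiny_net(), ct_of(c(1, -1, 0.5, 0.2)),
                               gene_map4)
  expect_equal(f2, -f1)
})

test_that("unmeasured downstream genes are excluded with a warning", {
  ct <- ct_of(c(1, -1, 2, 2))[1:2]  # g3, g4 unmeasured
  expect_warning(f <- backbone_differentials(tiny_net(), ct, gene_map4[1:2]),
                 "no measured downstream")
  expect_equal(unname(f), c(1, 0))
  expect_error(
    backbone_differentials(tiny_net(),
                           data.table::data.table(feature_id = "zz",
                                                  logFC = 1),
                           data.table::data.table(feature_id = "zz",
                                                  gene = "nope")),
    "no overlap")
})

test_that("the amplitude is a quadratic form with the stated identities", {
  net <- tiny_net()
  f <- c(A = 1, B = -1)
  # edge sign +1 disagrees: (1-(-1))^2 / 1 edge + (1+1)/2 nodes
  expect_equal(npa_amplitude(f, net$edges), 4 + 1)
  expect_equal(npa_amplitude(c(A = 0, B = 0), net$edges), 0)
  # scaling fold changes by c scales the amplitude by c^2
  expect_equal(npa_amplitude(3 * f, net$edges), 9 * npa_amplitude(f, net$edges))
  # node relabeling leaves the amplitude unchanged
  net2 <- net
  net2$edges <- data.table::data.table(from = "B", to = "A", sign = 1,
                                       weight = 1)
  expect_equal(npa_amplitude(f, net2$edges), npa_amplitude(f, net$edges))
})

test_that("zero signal gives zero amplitude and null permutation p-values", {
  st <- fx_cached("small_study", simulate_study(fx_small_config(seed = 5)))
  net <- simulate_causal_network(st, n_backbone = 6, n_downstream = 8,
                                 seed = 2)
  ct <- data.table::data.table(
    feature_id = st$layers$mRNA$annotations$feature_id, logFC = 0)
  r <- npa_score(net, ct, st$layers$mRNA$annotations, n_perm = 100,
                 seed = 1)
  expect_equal(r$npa, 0)
  expect_gt(r$p_O, 0.9)
  expect_gt(r$p_K, 0.9)
  expect_error(npa_score(net, ct, st$layers$mRNA$annotations, n_perm = 50),
               "unstable")
})

test_that("a planted coherent perturbation is significant in all statistics", {
  st <- fx_study()
  net <- simulate_causal_network(st, seed = 3)
  layers <- fx_layers()
  ct <- fx_contrasts_3r4f()$mRNA
  r <- npa_score(net, ct, layers$mRNA$annotations, n_perm = 500, seed = 1,
                 layer = layers$mRNA, sheet = st$sheet)
  expect_lt(r$p_O, 0.05)
  expect_lt(r$p_K, 0.05)
  expect_lt(r$p_replicates, 0.05)
  expect_true(r$significant)
  expect_true(r$ci[1] <= r$npa && r$npa <= r$ci[2])
})

test_that("permutation p-values are uniform under an i.i.d. Gaussian null", {
  st <- fx_cached("small_study", simulate_study(fx_small_config(seed = 5)))
  net <- simulate_causal_network(st, n_backbone = 6, n_downstream = 8,
                                 seed = 2)
  ps <- t(vapply(1:20, function(s) {
    set.seed(1000 + s)
    ct <- data.table::data.table(
      feature_id = st$layers$mRNA$annotations$feature_id,
      logFC = stats::rnorm(nrow(st$layers$mRNA$annotations)))
    r <- npa_score(net, ct, st$layers$mRNA$annotations, n_perm = 199,
                   seed = s)
    c(r$p_O, r$p_K)
  }, c(0, 0)))
  expect_gt(suppressWarnings(stats::ks.test(ps[, 1], "punif")$p.value),
            0.01)
  expect_gt(suppressWarnings(stats::ks.test(ps[, 2], "punif")$p.value),
            0.01)
})

test_that("impact factors aggregate and rescale as defined", {
  mk <- function(npa, sig = TRUE) {
    structure(list(npa = npa, significant = sig), class = "npa_result")
  }
  res <- list(net1 = list(c1 = mk(4), c2 = mk(1), c3 = mk(0)))
  out <- bif_aggregate(res)
  expect_equal(out$rbif, c(100, 25, 0))
  # single contrast
  out1 <- bif_aggregate(list(net1 = list(only = mk(2))))
  expect_equal(out1$rbif, 100)
  # non-significant amplitudes contribute zero
  res2 <- list(net1 = list(c1 = mk(4), c2 = mk(8, sig = FALSE)))
  expect_equal(bif_aggregate(res2)$rbif, c(100, 0))
  # permuting contrast order permutes the output identically
  res3 <- list(net1 = list(c3 = mk(0), c1 = mk(4), c2 = mk(1)))
  out3 <- bif_aggregate(res3)
  expect_equal(out3$rbif[match(out$contrast, out3$contrast)], out$rbif)
  # all-zero amplitudes flagged
  res4 <- list(net1 = list(c1 = mk(0), c2 = mk(0)))
  out4 <- bif_aggregate(res4)
  expect_equal(attr(out4, "status"), "all-zero")
  expect_equal(out4$rbif, c(0, 0))
})
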