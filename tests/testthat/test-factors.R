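test_that("noiseless rank-1 data is recovered by a single factor", {
  cfg <- one_factor_config(seed = 3, noise = 0,
                           dims = c(mRNA = 60, protein = 30, metabolite = 30,
                                    lipid = 30, miRNA = 30))
  st <- simulate_study(cfg)
  layers <- lapply(st$layers, preprocess_layer, sheet = st$sheet)
  fm <- fit_mofa(layers, st$sheet, k_init = 5, seed = 1)
  # ARD retires all but the planted factor far above the drop threshold
  expect_gt(fm$r2["mRNA", 1], 0.99)
  if (ncol(fm$Z) > 1) expect_lt(max(fm$r2[, -1]), 0.01)
  cc <- abs(stats::cor(fm$Z[, 1], st$truth$scores[, 1]))
  expect_gt(cc, 0.999)
})

test_that("the ELBO is non-decreasing on the default study", {
  fm <- fx_model()
  d <- diff(fm$elbo)
  expect_true(all(d > -1e-6 * abs(fm$elbo[-1])))
})

test_that("the default study reproduces the planted group ordering", {
  st <- fx_study()
  fm <- fx_model()
  z1 <- align_sign(fm$Z[, 1], st$truth$scores[, 1])
  gm <- tapply(z1, st$sheet$group, mean)
  expect_gt(gm[["3R4F"]], max(gm[["Cessation"]], gm[["Switch"]]))
  expect_gt(min(gm[["Cessation"]], gm[["Switch"]]),
            max(gm[["Sham"]], gm[["CHTP"]], gm[["THS"]]))
  sham_like <- gm[c("Sham", "CHTP", "THS")]
  expect_lt(diff(range(sham_like)), 0.35 * (gm[["3R4F"]] - min(sham_like)))
})

test_that("modality-specific factors land in their modalities", {
  fm <- fx_model()
  r2 <- fm$r2
  # factor 1 shared: explains variance in every modality
  expect_true(all(r2[, 1] > 0.02))
  # factors 2 and 3 (by variance order) are the metabolite- and
  # lipid-specific nuisance factors
  expect_equal(rownames(r2)[which.max(r2[, 2])], "metabolite")
  expect_equal(rownames(r2)[which.max(r2[, 3])], "lipid")
})

test_that("permuting sample order permutes scores and leaves weights", {
  st <- fx_cached("small_study", simulate_study(fx_small_config(seed = 5)))
  layers <- lapply(st$layers, preprocess_layer, sheet = st$sheet)
  set.seed(42)
  perm <- sample(ncol(layers$mRNA$mat))
  layers_p <- lapply(layers, function(l) {
    l$mat <- l$mat[, perm, drop = FALSE]; l
  })
  f1 <- fit_mofa(layers, k_init = 4, seed = 1)
  f2 <- fit_mofa(layers_p, k_init = 4, seed = 1)
  expect_equal(ncol(f1$Z), ncol(f2$Z))
  expect_equal(unname(f2$Z), unname(f1$Z[perm, , drop = FALSE]),
               tolerance = 1e-6)
  expect_equal(f1$W$protein, f2$W$protein, tolerance = 1e-6)
})

test_that("variance explained is bounded and totals behave", {
  fm <- fx_model()
  ve <- variance_explained(fm)
  expect_true(all(ve$r2 >= 0 & ve$r2 <= 1))
  tot <- ve[factor == "total"]
  expect_equal(nrow(tot), 5)
  per <- ve[factor != "total"]
  # each per-factor r2 cannot exceed the modality total by construction
  for (m in tot$modality) {
    expect_lte(max(per[modality == m]$r2), tot[modality == m]$r2 + 1e-8)
  }
})

test_that("sGCCA enforces exactly `keep` nonzero loadings per modality", {
  st <- fx_cached("small_study", simulate_study(fx_small_config(seed = 5)))
  layers <- lapply(st$layers, preprocess_layer, sheet = st$sheet)
  sg <- suppressMessages(fit_sgcca(layers, keep = 10, ncomp = 2))
  for (m in names(sg$loadings)) {
    expect_equal(colSums(sg$loadings[[m]] != 0), c(10, 10),
                 ignore_attr = TRUE)
    expect_equal(colSums(sg$loadings[[m]]^2), c(1, 1), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # keep = all features: no zeros forced, unit norm
  sg2 <- suppressMessages(fit_sgcca(layers["miRNA" != names(layers)][1:2],
                                    keep = c(mRNA = 300, protein = 100),
                                    ncomp = 1))
  expect_gt(sum(sg2$loadings$mRNA[, 1] != 0), 290)
  expect_equal(sum(sg2$loadings$mRNA[, 1]^2), 1, tolerance = 1e-8)
  expect_error(suppressMessages(fit_sgcca(layers, keep = 1e4)), "keep")
})

test_that("sGCCA component 1 agrees with the factor model's top weights", {
  st <- fx_study()
  layers <- fx_layers()
  fm <- fx_model()
  sg <- suppressMessages(fit_sgcca(layers, keep = 30, ncomp = 1))
  top_sg <- rownames(fm$W$mRNA)[abs(sg$loadings$mRNA[, 1]) > 0]
  top_fm <- rownames(fm$W$mRNA)[order(-abs(fm$W$mRNA[, 1]))][1:30]
  ov <- length(intersect(top_sg, top_fm))
  n <- nrow(fm$W$mRNA)
  p <- stats::phyper(ov - 1, 30, n - 30, 30, lower.tail = FALSE)
  expect_lt(p, 0.01)
})

test_that("PCA of a layer reports sane variance percentages", {
  layers <- fx_layers()
  pc <- pca_layer(layers$mRNA)
  expect_lte(sum(pc$percent_var), 100 + 1e-8)
  expect_true(all(diff(pc$percent_var) <= 1e-8))
  # rank-1 noiseless layer concentrates on PC1
  cfg <- one_factor_config(seed = 4, noise = 0,
                           dims = c(mRNA = 40, protein = 20, metabolite = 20,
                                    lipid = 20, miRNA = 20))
  st0 <- simulate_study(cfg)
  l0 <- preprocess_layer(st0$layers$mRNA, st0$sheet)
  pc0 <- pca_layer(l0)
  expect_equal(pc0$percent_var[1], 100, tolerance = 1e-6)
  # duplicating every sample leaves the leading direction unchanged
  l2 <- layers$mRNA
  l2$mat <- cbind(l2$mat, l2$mat)
  colnames(l2$mat) <- make.unique(colnames(l2$mat))
  pc2 <- pca_layer(l2)
  expect_equal(abs(stats::cor(pc$scores[, 1],
                              pc2$scores[seq_len(nrow(pc$scores)), 1])), 1,
               tolerance = 1e-6)
})

test_that("factor-covariate correlation is exact for affine covariates", {
  st <- fx_cached("small_study", simulate_study(fx_small_config(seed = 5)))
  fake <- list(Z = matrix(stats::rnorm(nrow(st$sheet)), ncol = 1,
                          dimnames = list(st$sheet$sample_id, "factor1")))
  class(fake) <- "factor_model"
  sheet <- data.table::copy(st$sheet)
  sheet[, balf_total_cells := 10 + 3 * fake$Z[, 1]]
  res <- correlate_factor_covariate(fake, sheet)
  expect_equal(res$r2, 1, tolerance = 1e-9)
  expect_gt(res$slope, 0)
  expect_error(correlate_factor_covariate(fake, sheet[group == "Sham" &
                                                        timepoint == 3]),
               "fewer than 3")
})

test_that("covariate correlation is weak when the covariate is independent", {
  st <- fx_cached("small_study", simulate_study(fx_small_config(seed = 5)))
  r2s <- vapply(1:20, function(s) {
    set.seed(s)
    fake <- list(Z = matrix(stats::rnorm(nrow(st$sheet)), ncol = 1,
                            dimnames = list(st$sheet$sample_id, "factor1")))
    class(fake) <- "factor_model"
    sheet <- data.table::copy(st$sheet)
    sheet[, balf_total_cells := stats::rnorm(.N, 50, 10)]
    correlate_factor_covariate(fake, sheet)$r2
  }, 0)
  expect_lt(mean(r2s), 0.2)
})

test_that("the factor-1 covariate slope matches the planted direction", {
  st <- fx_study()
  fm <- fx_model()
  aligned <- fm
  flip <- sign(stats::cor(fm$Z[, 1], st$truth$scores[, 1]))
  aligned$Z[, 1] <- fm$Z[, 1] * flip
  res <- correlate_factor_covariate(aligned, st$sheet)
  expect_equal(sign(res$slope), sign(st$truth$balf$slope))
  expect_gt(res$r2, 0.8)
})
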