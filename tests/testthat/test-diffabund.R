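make_sheet <- function(ids, modality, avail = TRUE) {
  dt <- data.table::data.table(sample_id = ids, group = "Sham",
                               timepoint = 3, animal = seq_along(ids))
  dt[[paste0("avail_", modality)]] <- avail
  dt
}

test_that("metabolite missing values are imputed as the feature minimum", {
  mat <- matrix(c(2.0, NA, 5.0), 1, 3,
                dimnames = list("Met0001", c("s1", "s2", "s3")))
  lay <- omics_layer("metabolite", mat,
                     data.table::data.table(feature_id = "Met0001",
                                            gene = NA, node_id = "Met0001"))
  out <- preprocess_layer(lay, make_sheet(c("s1", "s2", "s3"), "metabolite"))
  expect_equal(unname(2^out$mat[1, ]), c(2, 2, 5))
})

test_that("metabolites with no observed value are dropped with a warning", {
  mat <- matrix(c(2, NA, 4, NA, NA, NA), 2, 3, byrow = TRUE,
                dimnames = list(c("Met0001", "Met0002"),
                                c("s1", "s2", "s3")))
  lay <- omics_layer("metabolite", mat,
                     data.table::data.table(feature_id = c("Met0001",
                                                           "Met0002"),
                                            gene = NA, node_id = NA))
  expect_warning(
    out <- preprocess_layer(lay, make_sheet(c("s1", "s2", "s3"),
                                            "metabolite")),
    "cannot impute")
  expect_equal(nrow(out$mat), 1)
})

test_that("lipids are normalized per total protein before log2", {
  mat <- matrix(10, 1, 1, dimnames = list("Lip0001", "s1"))
  lay <- omics_layer("lipid", mat,
                     data.table::data.table(feature_id = "Lip0001",
                                            gene = NA, node_id = NA),
                     total_protein = c(s1 = 2))
  out <- preprocess_layer(lay, make_sheet("s1", "lipid"))
  expect_equal(unname(2^out$mat[1, 1]), 5)
})

test_that("log2-scale layers pass through preprocessing unchanged", {
  st <- fx_cached("small_study", simulate_study(fx_small_config(seed = 5)))
  out <- preprocess_layer(st$layers$mRNA, st$sheet)
  expect_identical(out$mat, st$layers$mRNA$mat)
})

test_that("prior estimation matches the moment-matching oracle", {
  set.seed(10)
  d0 <- 6; s02 <- 2; d <- 8
  s2 <- s02 * d0 * stats::rchisq(3000, d) / (d * stats::rchisq(3000, d0))
  pr <- estimate_prior(s2, d)
  ora <- limma::fitFDist(s2, df1 = d)
  expect_equal(pr$d0, ora$df2, tolerance = 1e-6)
  expect_equal(pr$s02, ora$scale, tolerance = 1e-6)
})

test_that("identical variances give an infinite prior at the common value", {
  pr <- estimate_prior(rep(2.5, 50), d = 10)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s02, 2.5)
  expect_equal(posterior_variance(pr, c(1, 9), 10), c(2.5, 2.5))
})

test_that("posterior variances interpolate between prior and sample", {
  pr <- ebayes_prior(4, 2)
  s2 <- c(0.5, 2, 8)
  post <- posterior_variance(pr, s2, 10)
  expect_true(all(post >= pmin(s2, 2) & post <= pmax(s2, 2)))
  expect_equal(posterior_variance(ebayes_prior(0, 1), s2, 10), s2)
})

test_that("moderated t with d0 = 0 equals the ordinary pooled t", {
  st <- fx_cached("small_study", simulate_study(fx_small_config(seed = 5)))
  lay <- preprocess_layer(st$layers$protein, st$sheet)
  ct <- fit_contrast(lay, st$sheet, "3R4F", 3, prior = ebayes_prior(0, 1))
  i <- which(ct$feature_id == ct$feature_id[5])
  f <- ct$feature_id[i]
  avail <- st$sheet$avail_protein
  x <- lay$mat[f, st$sheet$sample_id[st$sheet$group == "3R4F" &
                                       st$sheet$timepoint == 3 & avail]]
  y <- lay$mat[f, st$sheet$sample_id[st$sheet$group == "Sham" &
                                       st$sheet$timepoint == 3 & avail]]
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(ct$t[i], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(ct$P.Value[i], tt$p.value, tolerance = 1e-12)
})

test_that("null contrasts stay calibrated under BH", {
  frac <- vapply(1:20, function(s) {
    set.seed(s)
    mat <- matrix(stats::rnorm(400 * 18), 400, 18)
    ids <- sprintf("s%02d", 1:18)
    colnames(mat) <- ids
    rownames(mat) <- sprintf("f%03d", 1:400)
    lay <- omics_layer("mRNA", mat,
                       data.table::data.table(feature_id = rownames(mat),
                                              gene = NA, node_id = NA))
    sheet <- data.table::data.table(
      sample_id = ids, group = rep(c("X", "Sham"), each = 9),
      timepoint = 3, animal = 1:18, avail_mRNA = TRUE)
    ct <- fit_contrast(lay, sheet, "X", 3)
    mean(ct$significant)
  }, 0)
  expect_lte(mean(frac), 0.05)
})

test_that("planted features are preferentially detected", {
  st <- fx_study()
  ct <- fx_contrasts_3r4f()$mRNA
  act <- st$truth$active$mRNA[, 1]
  sig <- ct$significant[match(st$layers$mRNA$annotations$feature_id,
                              ct$feature_id)]
  expect_gt(mean(sig[act]), mean(sig[!act]))
})

test_that("an arm with fewer than two samples skips the contrast", {
  st <- fx_cached("small_study", simulate_study(fx_small_config(seed = 5)))
  lay <- st$layers$mRNA
  sheet <- data.table::copy(st$sheet)
  sheet[group == "3R4F" & timepoint == 3 & animal > 1, avail_mRNA := FALSE]
  expect_warning(out <- fit_contrast(lay, sheet, "3R4F", 3), "skipped")
  expect_null(out)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.123), 0.123)
  set.seed(1)
  for (i in 1:20) {
    p <- stats::runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
    expect_true(all(bh_adjust(p) >= p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("BH is invariant to appended p = 1 entries up to family size", {
  set.seed(2)
  p <- stats::runif(10)
  a <- bh_adjust(p)
  b <- bh_adjust(c(p, 1))
  # oracle comparison at the enlarged family size
  expect_equal(b, bh_oracle(c(p, 1)))
  expect_equal(order(a), order(b[1:10]))
})

test_that("cross-modal fold-change correlation behaves at its extremes", {
  ann <- data.table::data.table(feature_id = sprintf("f%d", 1:100),
                                gene = sprintf("G%d", 1:100))
  fc <- stats::rnorm(100)
  ta <- data.table::data.table(feature_id = ann$feature_id, logFC = fc)
  res <- suppressWarnings(crossmodal_fc_correlation(ta, ta, ann, ann))
  expect_equal(res$r2, 1, tolerance = 1e-12)
  expect_equal(res$slope, 1, tolerance = 1e-12)
  r2s <- vapply(1:20, function(s) {
    set.seed(s)
    ann2 <- data.table::data.table(feature_id = sprintf("f%d", 1:1000),
                                   gene = sprintf("G%d", 1:1000))
    a <- data.table::data.table(feature_id = ann2$feature_id,
                                logFC = stats::rnorm(1000))
    b <- data.table::data.table(feature_id = ann2$feature_id,
                                logFC = stats::rnorm(1000))
    crossmodal_fc_correlation(a, b, ann2, ann2)$r2
  }, 0)
  expect_lt(mean(r2s), 0.02)
  expect_error(crossmodal_fc_correlation(ta[1:2], ta[1:2], ann, ann),
               "fewer than 3")
})

test_that("significant counts equal the number of flags", {
  tabs <- list(mRNA = list("3R4F@6" = fx_contrasts_3r4f()$mRNA))
  cnt <- count_significant(tabs)
  expect_equal(cnt$n_significant, sum(fx_contrasts_3r4f()$mRNA$significant))
  expect_equal(cnt$modality, "mRNA")
})
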