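# Unsupervised multi-omics integration: the ARD latent factor model with
# missing-block handling, variance explained per modality and factor, the
# sparse generalized canonical correlation cross-check, per-modality PCA,
# and the factor-1 / BALF immune-cell-count association.

source("analysis/00_common.R")

fm <- factor_model()
ve <- variance_explained(fm)
write_tsv(ve, file.path(RESULTS_DIR, "variance_explained.tsv"))
scores <- data.table::data.table(sample_id = rownames(fm$Z))
write_tsv(cbind(scores, data.table::as.data.table(fm$Z)),
          file.path(RESULTS_DIR, "factor_scores.tsv"))
for (m in names(fm$W)) {
  w <- data.table::data.table(feature_id = rownames(fm$W[[m]]))
  write_tsv(cbind(w, data.table::as.data.table(fm$W[[m]])),
            file.path(RESULTS_DIR, "weights", paste0(m, ".tsv")))
}

cat("Latent factor model:", ncol(fm$Z), "factors retained after",
    length(fm$elbo), "iterations\n")
cat("Variance explained (%):\n")
print(round(100 * fm$r2[, 1:min(4, ncol(fm$r2))], 1))
gm <- tapply(fm$Z[, 1], study()$sheet$group, mean)
cat("\nFactor-1 group means:\n")
print(round(gm[order(-abs(gm))], 2))

sg <- fit_sgcca(layers(), keep = 30, ncomp = 2)
top_sg <- rownames(fm$W$mRNA)[abs(sg$loadings$mRNA[, 1]) > 0]
top_fm <- rownames(fm$W$mRNA)[order(-abs(fm$W$mRNA[, 1]))][1:30]
cat("\nsGCCA: component-1 mRNA variates overlapping the factor model's",
    "top 30:", length(intersect(top_sg, top_fm)), "of 30\n")

cc <- correlate_factor_covariate(fm, study()$sheet)
write_tsv(cc$means, file.path(RESULTS_DIR, "balf_correlation.tsv"))
cat("\nFactor 1 vs BALF total immune cells: R2 =", round(cc$r2, 3),
    ", slope sign", sign(cc$slope), "\n")

pca <- data.table::rbindlist(lapply(names(layers()), function(m) {
  p <- pca_layer(layers()[[m]])
  data.table::data.table(modality = m, pc1_pct = p$percent_var[1],
                         pc2_pct = p$percent_var[2])
}))
write_tsv(pca, file.path(RESULTS_DIR, "pca_variance.tsv"))
cat("\nPer-modality PCA (percent variance, PC1/PC2):\n")
print(pca)
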