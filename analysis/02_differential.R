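# Per-modality differential abundance versus Sham with empirical-Bayes
# moderated t-statistics and BH-FDR, the per-contrast significance counts,
# and the gene-matched mRNA/protein fold-change correlation.

source("analysis/00_common.R")

tables <- contrast_tables()
counts <- count_significant(tables)
write_tsv(counts, file.path(RESULTS_DIR, "differential_counts.tsv"))

for (m in names(tables)) {
  for (nm in names(tables[[m]])) {
    ct <- tables[[m]][[nm]]
    write_tsv(ct[, .(feature_id, logFC, t, P.Value, adj.P.Val, significant)],
              file.path(RESULTS_DIR, "contrasts",
                        sprintf("%s_%s.tsv", m, gsub("@", "_", nm))))
  }
}

cat("Differentially abundant features (FDR < 0.05), smoke exposure arm:\n")
print(counts[group == "3R4F"])

fc <- data.table::rbindlist(lapply(c(3, 4, 6), function(tp) {
  r <- crossmodal_fc_correlation(
    tables$mRNA[[paste0("3R4F@", tp)]],
    tables$protein[[paste0("3R4F@", tp)]],
    layers()$mRNA$annotations, layers()$protein$annotations)
  data.table::data.table(timepoint = tp, r2 = r$r2, slope = r$slope,
                         n = r$n)
}))
write_tsv(fc, file.path(RESULTS_DIR, "fc_correlation.tsv"))
cat("\nmRNA/protein fold-change correlation (3R4F vs Sham):\n")
print(fc)
cat("mean R2:", round(mean(fc$r2), 3), "\n")
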