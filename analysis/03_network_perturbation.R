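# Causal-network perturbation scoring of the transcriptome contrasts:
# backbone differential values, quadratic perturbation amplitudes with the
# replicate/downstream/topology companion statistics, and aggregation into
# relative biological impact factors.

source("analysis/00_common.R")

cnet <- simulate_causal_network(study(),
                                seed = stage_seed(GLOBAL_SEED, "causal"))
tables <- contrast_tables()$mRNA

npa <- lapply(tables, function(ct) {
  npa_score(cnet, ct, layers()$mRNA$annotations, n_perm = 500,
            seed = stage_seed(GLOBAL_SEED, "npa"),
            layer = layers()$mRNA, sheet = study()$sheet)
})

npa_tab <- data.table::rbindlist(lapply(names(npa), function(nm) {
  r <- npa[[nm]]
  data.table::data.table(contrast = nm, npa = r$npa, ci_lo = r$ci[1],
                         ci_hi = r$ci[2], p_replicates = r$p_replicates,
                         p_O = r$p_O, p_K = r$p_K,
                         significant = r$significant)
}))
write_tsv(npa_tab, file.path(RESULTS_DIR, "npa.tsv"))

rbif <- bif_aggregate(list(lung_network = npa))
write_tsv(rbif, file.path(RESULTS_DIR, "rbif.tsv"))

cat("Network perturbation amplitudes (transcriptome):\n")
print(npa_tab[order(-npa)][1:6])
cat("\nRelative biological impact factors:\n")
print(rbif[order(-rbif)])
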