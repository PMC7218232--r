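# Functional interpretation of the exposure factor: preranked gene-set
# enrichment of the mRNA and protein weight vectors, and Fisher
# overrepresentation of the network terminals.

source("analysis/00_common.R")

gsets <- simulate_genesets(study(),
                           seed = stage_seed(GLOBAL_SEED, "genesets"))
fm <- factor_model()

for (m in c("mRNA", "protein")) {
  wv <- fm$W[[m]][, 1]
  names(wv) <- layers()[[m]]$annotations$gene
  res <- gsea_preranked(wv, gsets, n_perm = 1000,
                        seed = stage_seed(GLOBAL_SEED, "gsea"))
  write_tsv(res, file.path(RESULTS_DIR, paste0("gsea_", m, ".tsv")))
  cat("Top 5 enriched sets for the factor-1", m, "weights:\n")
  print(utils::head(res[, .(set, size, es, nes, pval, padj)], 5))
  cat("\n")
}

terms <- select_terminals(fm, 1, node_map())
sel <- unique(terms[modality == "mRNA"]$node_id)
ora <- fisher_ora(sel, unique(layers()$mRNA$annotations$gene), gsets)
write_tsv(ora, file.path(RESULTS_DIR, "ora_terminals.tsv"))
cat("Overrepresentation of network terminals, top 5 sets:\n")
print(utils::head(ora, 5))
cat("\nSignal sets (planted enrichment) at FDR < 0.05:",
    sum(ora[startsWith(set, "SET_0") & as.integer(substr(set, 5, 7)) <= 10
            ]$padj < 0.05), "of 10\n")
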