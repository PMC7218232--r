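# Generate the synthetic five-modality inhalation study and its companion
# resources (interaction tables, gene sets, causal network), and write them
# under results/data/. The design: six exposure arms x three time points,
# nine animals per arm (eight for proteomics), no 4-month metabolomics,
# sporadic QC dropout, and three planted latent factors (a shared exposure
# factor plus metabolite- and lipid-specific nuisance factors).

source("analysis/00_common.R")

st <- study()
outdir <- file.path(RESULTS_DIR, "data")
write_study(st, outdir)

ints <- simulate_interactions(st, seed = stage_seed(GLOBAL_SEED,
                                                    "interactions"))
write_tsv(ints, file.path(outdir, "interactions.tsv"))

gs <- simulate_genesets(st, seed = stage_seed(GLOBAL_SEED, "genesets"))
write_gmt(gs, file.path(outdir, "genesets.gmt"))

cnet <- simulate_causal_network(st, seed = stage_seed(GLOBAL_SEED, "causal"))
write_causal_network(cnet, file.path(outdir, "causal_network.json"))

avail <- colSums(as.matrix(
  st$sheet[, grepl("^avail_", names(st$sheet)), with = FALSE]))
cat("Simulated study:\n")
cat("  samples:", nrow(st$sheet), "(animal x time point)\n")
cat("  features:",
    paste(names(st$layers), vapply(st$layers, function(l) nrow(l$mat), 0L),
          collapse = ", "), "\n")
cat("  measured sample/modality cells:\n")
print(avail)
cat("  interactions:", nrow(ints), "| gene sets:", length(gs),
    "| backbone nodes:", length(cnet$nodes), "\n")
cat("  planted factor-1 group means:\n")
print(round(tapply(st$truth$scores[, 1], st$sheet$group, mean), 2))
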