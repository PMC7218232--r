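# Shared setup for the numbered analysis scripts: one global seed expanded
# into per-stage substreams, and lazily built shared objects so each script
# can run standalone (everything is deterministic and cheap to rebuild).

suppressPackageStartupMessages(library(toxomix))

GLOBAL_SEED <- 1L
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

.an <- new.env(parent = emptyenv())
memo <- function(key, expr) {
  if (is.null(.an[[key]])) .an[[key]] <- force(expr)
  .an[[key]]
}

study <- function() memo("study", simulate_study(
  sim_config(seed = stage_seed(GLOBAL_SEED, "syndata"))))

layers <- function() memo("layers", {
  lapply(study()$layers, preprocess_layer, sheet = study()$sheet)
})

contrast_tables <- function() memo("tables", {
  fit_all_contrasts(layers(), study()$sheet)
})

factor_model <- function() memo("model", {
  fit_mofa(layers(), study()$sheet,
           seed = stage_seed(GLOBAL_SEED, "factors"))
})

interaction_network <- function() memo("network", {
  ints <- simulate_interactions(study(),
                                seed = stage_seed(GLOBAL_SEED,
                                                  "interactions"))
  assign_edge_weights(suppressMessages(filter_interactions(ints)))
})

node_map <- function() memo("node_map", {
  harmonize_ids(layers(), interaction_network())
})
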