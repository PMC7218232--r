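#' Default pipeline configuration
#'
#' @param seed Global seed (expanded into per-stage substreams).
#' @param outdir Output directory.
#' @param syndata [sim_config()] overrides (list).
#' @param diffabund,npa,factors,pcsf,enrich Stage parameter lists.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("toxomix_run_"),
                            syndata = list(), diffabund = list(fdr = 0.05),
                            npa = list(n_perm = 500, n_boot = 200),
                            factors = list(k_init = 10, tol = 1e-6,
                                           drop_threshold = 0.001,
                                           keep = 30, ncomp = 2),
                            pcsf = list(mu = 5e-4, omega = 0.6, beta = 1000,
                                        runs = 10, r = 0.1,
                                        grid = FALSE),
                            enrich = list(n_perm = 1000, n_sets = 50,
                                          n_signal = 10, top_n = 20)) {
  structure(list(seed = as.integer(seed), outdir = outdir,
                 syndata = syndata, diffabund = diffabund, npa = npa,
                 factors = factors, pcsf = pcsf, enrich = enrich),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param config A `pipeline_config` (or a YAML path to one).
#' @return Character vector of problems (length 0 if clean).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) return("config file does not exist")
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  problems <- character(0)
  chk <- function(cond, msg) {
    if (!isTRUE(cond)) problems <<- c(problems, msg)
    invisible(NULL)
  }
  chk(is.numeric(config$seed) && length(config$seed) == 1 &&
        !is.na(config$seed),
      "seed: must be a single integer")
  sd <- config$syndata
  if (!is.null(sd$modality_dims)) {
    chk(all(c("mRNA", "protein", "metabolite", "lipid", "miRNA") %in%
              names(sd$modality_dims)),
        "syndata.modality_dims: missing modality dimension")
    chk(all(unlist(sd$modality_dims) > 0),
        "syndata.modality_dims: dimensions must be positive")
  }
  chk(is.null(config$pcsf$omega) || config$pcsf$omega >= 0,
      "pcsf.omega: must be >= 0")
  chk(is.null(config$pcsf$mu) || config$pcsf$mu >= 0,
      "pcsf.mu: must be >= 0")
  chk(is.null(config$pcsf$beta) || config$pcsf$beta >= 0,
      "pcsf.beta: must be >= 0")
  chk(is.null(config$pcsf$r) || config$pcsf$r >= 0,
      "pcsf.r: must be >= 0")
  chk(is.null(config$npa$n_perm) || config$npa$n_perm >= 100,
      "npa.n_perm: must be >= 100")
  chk(is.null(config$enrich$n_perm) || config$enrich$n_perm >= 1000,
      "enrich.n_perm: must be >= 1000")
  chk(is.null(config$factors$k_init) || config$factors$k_init >= 1,
      "factors.k_init: must be >= 1")
  problems
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Simulation, preprocessing, differential abundance, causal-network
#' perturbation scoring, latent-factor integration, sGCCA cross-check,
#' network assembly, terminal selection, (optional) grid search, randomized
#' ensemble Steiner forest, edge-betweenness clustering, cluster profiles,
#' and enrichment. All randomness derives from the global seed via named
#' per-stage substreams; all result tables are written as TSV under the
#' output directory along with a provenance manifest.
#'
#' @param config A [pipeline_config()].
#' @return A `report_bundle` list of result tables.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  problems <- validate_config(config)
  if (length(problems) > 0) {
    stop("invalid pipeline config:\n  ", paste(problems, collapse = "\n  "))
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(...)))
  }

  # --- simulate ---
  sc_args <- config$syndata
  sc_args$seed <- stage_seed(config$seed, "syndata")
  sc <- do.call(sim_config, sc_args)
  study <- simulate_study(sc)
  log_stage("syndata", "simulated ", length(study$layers), " modalities, ",
            nrow(study$sheet), " samples")
  write_study(study, file.path(outdir, "study"))

  # --- preprocess ---
  layers <- lapply(study$layers, preprocess_layer, sheet = study$sheet)

  # --- differential abundance ---
  tables <- fit_all_contrasts(layers, study$sheet,
                              fdr = config$diffabund$fdr %||% 0.05)
  n_contrasts <- sum(lengths(tables))
  counts <- if (n_contrasts > 0) count_significant(tables) else
    data.table::data.table()
  log_stage("diffabund", n_contrasts, " contrasts fitted")
  if (n_contrasts > 0) {
    write_tsv(counts, file.path(outdir, "differential_counts.tsv"))
  }
  fc_cor <- NULL
  if (!is.null(tables$mRNA[["3R4F@6"]]) &&
        !is.null(tables$protein[["3R4F@6"]])) {
    fc_cor <- crossmodal_fc_correlation(
      tables$mRNA[["3R4F@6"]], tables$protein[["3R4F@6"]],
      layers$mRNA$annotations, layers$protein$annotations)
  }

  # --- causal network perturbation ---
  rbif <- NULL; npa_results <- NULL
  mrna_contrasts <- tables$mRNA
  if (length(mrna_contrasts) > 0) {
    n_genes <- nrow(layers$mRNA$annotations)
    n_bb <- config$npa$n_backbone %||% 20
    n_ds <- min(config$npa$n_downstream %||% 25, n_genes %/% n_bb)
    cnet <- simulate_causal_network(study, n_backbone = n_bb,
                                    n_downstream = n_ds,
                                    seed = stage_seed(config$seed, "causal"))
    write_causal_network(cnet, file.path(outdir, "causal_network.json"))
    npa_results <- list(network1 = lapply(mrna_contrasts, function(ct) {
      npa_score(cnet, ct, layers$mRNA$annotations,
                n_perm = config$npa$n_perm %||% 500,
                seed = stage_seed(config$seed, "npa"),
                layer = layers$mRNA, sheet = study$sheet,
                n_boot = config$npa$n_boot %||% 200)
    }))
    rbif <- bif_aggregate(npa_results)
    write_tsv(rbif, file.path(outdir, "rbif.tsv"))
  }

  # --- factor model ---
  fm <- fit_mofa(layers, study$sheet,
                 k_init = config$factors$k_init %||% 10,
                 tol = config$factors$tol %||% 1e-6,
                 drop_threshold = config$factors$drop_threshold %||% 0.001,
                 seed = stage_seed(config$seed, "factors"))
  ve <- variance_explained(fm)
  log_stage("factors", ncol(fm$Z), " factors retained")
  write_tsv(ve, file.path(outdir, "variance_explained.tsv"))
  scores <- data.table::data.table(sample_id = rownames(fm$Z))
  scores <- cbind(scores, data.table::as.data.table(fm$Z))
  write_tsv(scores, file.path(outdir, "factor_scores.tsv"))

  sg <- fit_sgcca(layers, keep = config$factors$keep %||% 30,
                  ncomp = config$factors$ncomp %||% 2)
  cov_cor <- correlate_factor_covariate(fm, study$sheet)

  # --- network assembly ---
  interactions <- simulate_interactions(
    study, seed = stage_seed(config$seed, "interactions"))
  filtered <- suppressMessages(filter_interactions(interactions))
  log_stage("netbuild", nrow(filtered), " of ", nrow(interactions),
            " interactions kept")
  net <- assign_edge_weights(filtered)
  node_map <- harmonize_ids(layers, net)

  # --- terminals + PCSF ---
  terminals <- suppressMessages(select_terminals(fm, 1, node_map))
  log_stage("pcsf", nrow(terminals), " terminals selected")
  pc <- config$pcsf
  gs <- NULL
  cfg <- pcsf_config(mu = pc$mu %||% 5e-4, omega = pc$omega %||% 0.6,
                     beta = pc$beta %||% 1000, runs = pc$runs %||% 10,
                     r = pc$r %||% 0.1,
                     seed = stage_seed(config$seed, "pcsf"))
  if (isTRUE(pc$grid)) {
    gs <- grid_search(net, terminals, mu = cfg$mu)
    write_tsv(gs$curve, file.path(outdir, "grid_search.tsv"))
    cfg$omega <- gs$chosen$omega; cfg$beta <- gs$chosen$beta
  }
  single <- solve_pcsf(net, terminals, cfg)
  final_net <- ensemble_solve(net, terminals, cfg)
  log_stage("pcsf", igraph::vcount(final_net), " nodes / ",
            igraph::ecount(final_net), " edges in the ensemble network")

  # --- clustering + profiles ---
  clusters <- NULL; profiles <- NULL
  if (igraph::vcount(final_net) > 0) {
    clusters <- cluster_network(final_net)
    profiles <- cluster_profiles(clusters$membership, tables, node_map)
    write_tsv(profiles, file.path(outdir, "cluster_profiles.tsv"))
    igraph::V(final_net)$cluster <- as.integer(clusters$membership)
    write_network(final_net, file.path(outdir, "association_network"))
  }

  # --- enrichment ---
  genesets <- simulate_genesets(study,
                                n_sets = config$enrich$n_sets %||% 50,
                                n_signal = config$enrich$n_signal %||% 10,
                                seed = stage_seed(config$seed, "genesets"))
  write_gmt(genesets, file.path(outdir, "genesets.gmt"))
  wv <- fm$W$mRNA[, 1]
  names(wv) <- layers$mRNA$annotations$gene
  gsea <- gsea_preranked(wv, genesets,
                         n_perm = config$enrich$n_perm %||% 1000,
                         seed = stage_seed(config$seed, "gsea"))
  top_n <- config$enrich$top_n %||% 20
  write_tsv(utils::head(gsea, top_n), file.path(outdir, "gsea_top.tsv"))
  sel <- unique(terminals[modality == "mRNA"]$node_id)
  ora <- NULL
  if (length(sel) > 0) {
    ora <- fisher_ora(sel, unique(layers$mRNA$annotations$gene), genesets)
    write_tsv(utils::head(ora, top_n), file.path(outdir, "ora_top.tsv"))
  }

  # --- provenance manifest ---
  tsvs <- list.files(outdir, pattern = "\\.(tsv|gmt|json)$",
                     recursive = TRUE, full.names = TRUE)
  manifest <- list(
    seed = config$seed,
    stage_seeds = sapply(c("syndata", "causal", "npa", "factors",
                           "interactions", "pcsf", "genesets", "gsea"),
                         function(s) stage_seed(config$seed, s)),
    files = stats::setNames(as.list(unname(tools::md5sum(tsvs))),
                            basename(tsvs)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  structure(list(study = study, layers = layers, tables = tables,
                 counts = counts, fc_correlation = fc_cor,
                 npa = npa_results, rbif = rbif,
                 factor_model = fm, variance_explained = ve,
                 sgcca = sg, covariate_correlation = cov_cor,
                 network = net, node_map = node_map, terminals = terminals,
                 grid = gs, forest = single, final_network = final_net,
                 clusters = clusters, profiles = profiles,
                 gsea = gsea, ora = ora, manifest = manifest,
                 outdir = outdir),
            class = "report_bundle")
}
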