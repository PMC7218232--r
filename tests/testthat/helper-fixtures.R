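# shared fixtures, cached across test files (expensive fits run once)
.fx <- new.env(parent = emptyenv())

fx_cached <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

fx_study <- function() {
  fx_cached("study", simulate_study(sim_config(seed = 7)))
}

fx_layers <- function() {
  fx_cached("layers", {
    st <- fx_study()
    lapply(st$layers, preprocess_layer, sheet = st$sheet)
  })
}

fx_model <- function() {
  fx_cached("model", fit_mofa(fx_layers(), fx_study()$sheet, seed = 1))
}

fx_contrasts_3r4f <- function() {
  fx_cached("contrasts_3r4f", {
    st <- fx_study()
    lapply(fx_layers(), function(l) fit_contrast(l, st$sheet, "3R4F", 6))
  })
}

fx_network <- function() {
  fx_cached("network", {
    ints <- simulate_interactions(fx_study(), seed = 5)
    assign_edge_weights(suppressMessages(filter_interactions(ints)))
  })
}

fx_node_map <- function() {
  fx_cached("node_map", harmonize_ids(fx_layers(), fx_network()))
}

# a small fast study for cheap tests
fx_small_config <- function(seed = 1, ...) {
  sim_config(seed = seed,
             modality_dims = c(mRNA = 300, protein = 100, metabolite = 50,
                               lipid = 40, miRNA = 30), ...)
}

# single shared-factor configuration at a chosen noise level, on a fully
# observed design (two time points, equal replicates) so low-rank structure
# is exact
one_factor_config <- function(seed, noise, dims, score_sd = 0.5) {
  f1 <- planted_factor(
    1L,
    default_factors()[[1]]$group_effect,
    loading_scale = c(mRNA = 0.6, protein = 0.6, metabolite = 0.6,
                      lipid = 0.6, miRNA = 0.6),
    active_fraction = c(mRNA = 0.5, protein = 0.5, metabolite = 0.5,
                        lipid = 0.5, miRNA = 0.5),
    score_sd = score_sd)
  sim_config(seed = seed, modality_dims = dims, timepoints = c(3, 6),
             n_per_group_modality = c(mRNA = 9, protein = 9, metabolite = 9,
                                      lipid = 9, miRNA = 9),
             noise_sd = c(mRNA = noise, protein = noise, metabolite = noise,
                          lipid = noise, miRNA = noise),
             factors = list(f1),
             dropout_rate = 0, metabolite_censor_rate = 0)
}

# random small PCSF instances for oracle comparisons
random_pcsf_instance <- function(seed) {
  set.seed(seed)
  n <- sample(6:12, 1)
  m <- min(sample(8:16, 1), n * (n - 1) / 2)
  pairs <- t(utils::combn(n, 2))
  pairs <- pairs[sample(nrow(pairs), m), , drop = FALSE]
  ed <- data.frame(from = paste0("n", pairs[, 1]),
                   to = paste0("n", pairs[, 2]),
                   cost = round(stats::runif(m, 0.1, 1.1), 3))
  g <- igraph::graph_from_data_frame(
    ed, directed = FALSE, vertices = data.frame(name = paste0("n", 1:n)))
  nt <- sample(2:5, 1)
  terms <- data.table::data.table(
    node_id = paste0("n", sample(n, nt)),
    prize = round(stats::runif(nt, 0.2, 1), 3))
  cfg <- pcsf_config(mu = 0.0005, omega = stats::runif(1, 0.2, 1),
                     beta = stats::runif(1, 0.5, 2))
  list(net = g, terminals = terms, config = cfg)
}

# direct step-up BH oracle
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  prev <- Inf
  for (i in n:1) {
    prev <- min(prev, p[ord[i]] * n / i)
    adj[ord[i]] <- min(prev, 1)
  }
  adj
}

# independent running-sum enrichment score (re-derived for oracle use)
es_oracle <- function(stat, set) {
  o <- order(-stat, names(stat))
  s <- stat[o]
  hit <- names(s) %in% set
  ph <- cumsum(abs(s) * hit) / sum(abs(s)[hit])
  pm <- cumsum(!hit) / sum(!hit)
  d <- ph - pm
  unname(d[which.max(abs(d))])
}

# orient an estimated score vector to the planted one
align_sign <- function(z, z_true) z * sign(stats::cor(z, z_true))
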