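#' Planted latent factor specification
#'
#' Describes one planted factor of the synthetic study: its per-(group, time
#' point) mean score, per-modality loading scale and active fraction, the
#' within-group score standard deviation, and (for the exposure factor) the
#' correlation between loadings of gene-matched mRNA and protein features.
#'
#' @param id Integer factor id.
#' @param group_effect Numeric matrix `groups x timepoints` (dimnames required)
#'   of mean factor scores; missing cells default to 0.
#' @param loading_scale Named numeric vector, standard deviation of nonzero
#'   loadings per modality.
#' @param active_fraction Named numeric vector in (0, 1], fraction of features
#'   with nonzero loading per modality (modalities absent from the vector get
#'   fraction 0, i.e. the factor is inactive there).
#' @param score_sd Within-(group, timepoint) score standard deviation.
#' @param mrna_protein_loading_corr Correlation of factor loadings for
#'   gene-matched mRNA/protein features.
#' @return An object of class `planted_factor`.
#' @export
planted_factor <- function(id, group_effect, loading_scale, active_fraction,
                           score_sd = 0.5, mrna_protein_loading_corr = 0.72) {
  stopifnot(all(is.finite(group_effect)),
            all(active_fraction > 0), all(active_fraction <= 1))
  structure(list(id = id, group_effect = group_effect,
                 loading_scale = loading_scale,
                 active_fraction = active_fraction,
                 score_sd = score_sd,
                 mrna_protein_loading_corr = mrna_protein_loading_corr),
            class = "planted_factor")
}

#' Default planted factors of the synthetic study
#'
#' Factor 1 is the shared exposure factor: smoke exposure (3R4F) has the
#' extreme mean score at every time point; Cessation and Switch have
#' intermediate scores that decay over time (50% of the 3R4F score at 3
#' months, 25% at 6 months, linear-in-time in between); Sham and the two
#' heated-tobacco arms (CHTP, THS) sit at zero. Factors 2 and 3 are
#' modality-specific nuisance factors for the metabolite and lipid layers.
#'
#' @param groups,timepoints Study arms and time points (months).
#' @param effect_3r4f Mean factor-1 score of the 3R4F arm.
#' @return List of `planted_factor` objects.
#' @export
default_factors <- function(groups = c("Sham", "3R4F", "CHTP", "THS",
                                       "Cessation", "Switch"),
                            timepoints = c(3, 4, 6),
                            effect_3r4f = 3) {
  ge <- matrix(0, length(groups), length(timepoints),
               dimnames = list(groups, as.character(timepoints)))
  if ("3R4F" %in% groups) ge["3R4F", ] <- effect_3r4f
  # cessation/switch decay: 50% at 3 months -> 25% at 6 months, linear in time
  decay <- 0.5 + (0.25 - 0.5) * (timepoints - 3) / 3
  for (g in intersect(c("Cessation", "Switch"), groups)) {
    ge[g, ] <- effect_3r4f * decay
  }
  f1 <- planted_factor(
    1L, ge,
    loading_scale  = c(mRNA = 0.6, protein = 0.6, metabolite = 0.6,
                       lipid = 0.6, miRNA = 0.6),
    active_fraction = c(mRNA = 0.25, protein = 0.25, metabolite = 0.4,
                        lipid = 0.4, miRNA = 0.15),
    score_sd = 0.5)
  zero <- matrix(0, length(groups), length(timepoints),
                 dimnames = dimnames(ge))
  f2 <- planted_factor(2L, zero, c(metabolite = 0.8),
                       c(metabolite = 0.6), score_sd = 1.2)
  f3 <- planted_factor(3L, zero, c(lipid = 0.8),
                       c(lipid = 0.6), score_sd = 1.2)
  list(f1, f2, f3)
}

#' Synthetic study configuration
#'
#' Desk-scale emulation of a six-arm, three-time-point inhalation study with
#' five omics modalities. Feature counts default to a configurable scale-down
#' of a full study (where roughly 17,500 mRNAs, 5,000 proteins, 670
#' metabolites, 400 lipids and 360 miRNAs would be measured). Proteomics runs
#' on 8 of the 9 animals per group; metabolomics is not measured at the
#' 4-month time point; additional sporadic sample/modality dropouts emulate QC
#' exclusions.
#'
#' @param seed Integer seed; the whole study is reproducible from it.
#' @param groups Exposure arms.
#' @param timepoints Dissection time points in months.
#' @param n_per_group_modality Named vector of replicates per group and
#'   time point for each modality.
#' @param modality_dims Named vector of feature counts.
#' @param dropout_rate Probability that an available sample/modality cell is
#'   lost to QC beyond the design.
#' @param noise_sd Named vector of residual standard deviations (log2 scale).
#' @param factors List of [planted_factor()] objects.
#' @param metabolite_censor_rate Fraction of low-abundance metabolite values
#'   censored to missing within measured samples (imputed later during
#'   preprocessing).
#' @param balf Parameters of the synthetic BALF total immune cell count
#'   covariate (thousands of cells), an affine function of the factor-1 score
#'   truncated at zero.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       groups = c("Sham", "3R4F", "CHTP", "THS",
                                  "Cessation", "Switch"),
                       timepoints = c(3, 4, 6),
                       n_per_group_modality = c(mRNA = 9, protein = 8,
                                                metabolite = 9, lipid = 9,
                                                miRNA = 9),
                       modality_dims = c(mRNA = 2000, protein = 500,
                                         metabolite = 200, lipid = 150,
                                         miRNA = 100),
                       dropout_rate = 0.02,
                       noise_sd = c(mRNA = 0.8, protein = 0.7,
                                    metabolite = 0.8, lipid = 0.8,
                                    miRNA = 0.8),
                       factors = default_factors(groups, timepoints),
                       metabolite_censor_rate = 0.08,
                       balf = list(intercept = 50, slope = 40, sd = 8)) {
  if (any(modality_dims <= 0)) stop("modality dimensions must be positive")
  if (length(groups) == 0 || length(timepoints) == 0) {
    stop("groups and timepoints must be nonempty")
  }
  known <- c("mRNA", "protein", "metabolite", "lipid", "miRNA")
  if (!all(names(modality_dims) %in% known)) {
    stop("unknown modality in modality_dims: ",
         paste(setdiff(names(modality_dims), known), collapse = ", "))
  }
  if (any(n_per_group_modality < 2)) stop("need >=2 replicates per arm")
  structure(list(seed = as.integer(seed), groups = groups,
                 timepoints = timepoints,
                 n_per_group_modality = n_per_group_modality,
                 modality_dims = modality_dims,
                 dropout_rate = dropout_rate, noise_sd = noise_sd,
                 factors = factors,
                 metabolite_censor_rate = metabolite_censor_rate,
                 balf = balf),
            class = "sim_config")
}

#' One omics modality of a study
#'
#' @param modality Modality name.
#' @param mat Feature-by-sample matrix (NA = missing). mRNA/miRNA/protein are
#'   log2-scale; metabolite/lipid are raw positive scale until preprocessing.
#' @param annotations data.table with `feature_id`, `gene` (mRNA/protein) and
#'   `node_id` (network-mappable features).
#' @param total_protein Per-sample total protein amount in mg (lipid layer
#'   only), used for lipid normalization.
#' @return An object of class `omics_layer`.
#' @export
omics_layer <- function(modality, mat, annotations, total_protein = NULL) {
  stopifnot(nrow(mat) == nrow(annotations))
  structure(list(modality = modality, mat = mat, annotations = annotations,
                 total_protein = total_protein),
            class = "omics_layer")
}

feature_annotations <- function(dims) {
  n_genes <- dims[["mRNA"]]
  ann <- list()
  gene_ids <- sprintf("Gene%04d", seq_len(n_genes))
  ann$mRNA <- data.table::data.table(
    feature_id = sprintf("mRNA_%04d", seq_len(n_genes)),
    gene = gene_ids, node_id = gene_ids)
  if ("protein" %in% names(dims)) {
    np <- dims[["protein"]]
    if (np > n_genes) stop("more proteins than genes in the universe")
    ann$protein <- data.table::data.table(
      feature_id = sprintf("Prot_%04d", seq_len(np)),
      gene = gene_ids[seq_len(np)], node_id = gene_ids[seq_len(np)])
  }
  if ("metabolite" %in% names(dims)) {
    ids <- sprintf("Met%04d", seq_len(dims[["metabolite"]]))
    ann$metabolite <- data.table::data.table(
      feature_id = ids, gene = NA_character_, node_id = ids)
  }
  if ("lipid" %in% names(dims)) {
    ann$lipid <- data.table::data.table(
      feature_id = sprintf("Lip%04d", seq_len(dims[["lipid"]])),
      gene = NA_character_, node_id = NA_character_)
  }
  if ("miRNA" %in% names(dims)) {
    ids <- sprintf("Mir%04d", seq_len(dims[["miRNA"]]))
    ann$miRNA <- data.table::data.table(
      feature_id = ids, gene = NA_character_, node_id = ids)
  }
  ann
}

# factor loading matrices per modality, with gene-coupled mRNA/protein
# loadings for the exposure factor
simulate_loadings <- function(config) {
  dims <- config$modality_dims
  K <- length(config$factors)
  W <- lapply(dims, function(d) matrix(0, d, K))
  active <- lapply(dims, function(d) matrix(FALSE, d, K))
  n_prot <- if ("protein" %in% names(dims)) dims[["protein"]] else 0L
  for (k in seq_len(K)) {
    f <- config$factors[[k]]
    base_gene <- stats::rnorm(dims[["mRNA"]])  # shared gene-level effect
    for (m in names(dims)) {
      af <- f$active_fraction[m]
      sc <- f$loading_scale[m]
      if (is.na(af) || is.na(sc) || sc == 0) next
      d <- dims[[m]]
      if (m == "mRNA") {
        act <- stats::runif(d) < af
        W[[m]][act, k] <- sc * base_gene[act]
      } else if (m == "protein") {
        # same active mask and correlated loading as the matched mRNA genes
        af_m <- f$active_fraction["mRNA"]
        rho <- f$mrna_protein_loading_corr
        act <- if (!is.na(af_m)) {
          # recompute mRNA mask deterministically: stored below
          active[["mRNA"]][seq_len(d), k]
        } else stats::runif(d) < af
        e <- stats::rnorm(d)
        w <- rho * base_gene[seq_len(d)] + sqrt(1 - rho^2) * e
        W[[m]][act, k] <- sc * w[act]
      } else {
        act <- stats::runif(d) < af
        W[[m]][act, k] <- sc * stats::rnorm(sum(act))
      }
      active[[m]][, k] <- W[[m]][, k] != 0
    }
  }
  list(W = W, active = active)
}

#' Simulate a five-modality synthetic study
#'
#' Generates data per modality as `Y = W %*% t(Z) + noise` on the log2 model
#' scale with planted group/time-point factor scores, transforms the
#' metabolite and lipid layers to their native positive scales (lipid amounts
#' additionally scale with the sample's total protein), applies the design
#' missingness (8/9 proteomics replicates, no 4-month metabolomics) plus
#' random QC dropout, censors low-abundance metabolite values, and emits the
#' planted truth alongside the data.
#'
#' @param config A [sim_config()].
#' @return List with `layers` (named list of [omics_layer()]), `sheet`
#'   (sample sheet data.table) and `truth` (planted scores, loadings, masks
#'   and covariate parameters).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dims <- config$modality_dims
  groups <- config$groups
  tps <- config$timepoints
  n_animals <- max(config$n_per_group_modality)
  K <- length(config$factors)

  sheet <- data.table::CJ(timepoint = tps, group = groups,
                          animal = seq_len(n_animals), sorted = FALSE)
  data.table::setorder(sheet, timepoint, group, animal)
  sheet[, sample_id := sprintf("%s_T%d_A%02d", group, timepoint, animal)]
  N <- nrow(sheet)

  # planted factor scores
  Z <- matrix(0, N, K)
  for (k in seq_len(K)) {
    f <- config$factors[[k]]
    mu <- f$group_effect[cbind(match(sheet$group, rownames(f$group_effect)),
                               match(as.character(sheet$timepoint),
                                     colnames(f$group_effect)))]
    mu[is.na(mu)] <- 0
    Z[, k] <- mu + stats::rnorm(N, 0, f$score_sd)
  }
  colnames(Z) <- paste0("factor", seq_len(K))

  load <- simulate_loadings(config)
  ann <- feature_annotations(dims)

  # availability: design + random dropout
  for (m in names(dims)) {
    nm <- config$n_per_group_modality[[m]]
    avail <- sheet$animal <= nm
    if (m == "metabolite") avail <- avail & sheet$timepoint != 4
    if (config$dropout_rate > 0) {
      avail <- avail & (stats::runif(N) >= config$dropout_rate)
    }
    sheet[, paste0("avail_", m) := avail]
  }

  total_protein <- stats::runif(N, 1.5, 2.5)  # mg per sample
  names(total_protein) <- sheet$sample_id

  intercept_mu <- c(mRNA = 7, protein = 5, metabolite = 10, lipid = 4,
                    miRNA = 6)
  layers <- list()
  for (m in names(dims)) {
    d <- dims[[m]]
    mu0 <- stats::rnorm(d, intercept_mu[[m]], 1)
    Y <- mu0 + load$W[[m]] %*% t(Z) +
      matrix(stats::rnorm(d * N, 0, config$noise_sd[[m]]), d, N)
    colnames(Y) <- sheet$sample_id
    rownames(Y) <- ann[[m]]$feature_id
    if (m %in% c("metabolite", "lipid")) {
      Y <- 2^Y  # native positive scale
      if (m == "lipid") Y <- sweep(Y, 2, total_protein, `*`)
    }
    Y[, !sheet[[paste0("avail_", m)]]] <- NA_real_
    if (m == "metabolite" && config$metabolite_censor_rate > 0) {
      obs_cols <- which(sheet$avail_metabolite)
      for (i in seq_len(d)) {
        v <- Y[i, obs_cols]
        thr <- stats::quantile(v, config$metabolite_censor_rate,
                               names = FALSE)
        cens <- v < thr & v < max(v)  # always keep at least the maximum
        Y[i, obs_cols[cens]] <- NA_real_
      }
    }
    layers[[m]] <- omics_layer(m, Y, ann[[m]],
                               if (m == "lipid") total_protein else NULL)
  }

  # BALF total immune cell covariate: affine in factor-1 score, truncated at 0
  balf <- pmax(0, config$balf$intercept + config$balf$slope * Z[, 1] +
                    stats::rnorm(N, 0, config$balf$sd))
  sheet[, balf_total_cells := balf]

  truth <- list(
    scores = Z,
    sample_id = sheet$sample_id,
    loadings = load$W,
    active = load$active,
    group_effect = lapply(config$factors, `[[`, "group_effect"),
    balf = config$balf,
    seed = config$seed)
  list(layers = layers, sheet = sheet, truth = truth)
}

#' Simulate an interaction table emulating KEGG, STRING and mirTarBase
#'
#' Emits metabolite-enzyme links (kegg), scored gene-gene links (string) and
#' miRNA-target links with publication and non-high-throughput method counts
#' (mirtarbase). A configurable connectivity enrichment makes features loaded
#' on the planted exposure factor more connected than chance, so the
#' downstream Steiner forest has recoverable structure; enrichment 0 yields
#' chance-level connectivity.
#'
#' @param study Output of [simulate_study()] (the planted truth identifies
#'   exposure-factor features).
#' @param n_string,n_kegg,n_mirtarbase Numbers of links sampled per source.
#' @param score_range Range of STRING combined scores (uniform).
#' @param connectivity_enrichment Sampling weight multiplier (1 +
#'   enrichment) for factor-1-active nodes.
#' @param seed Integer seed.
#' @return data.table with columns `source_id`, `target_id`, `source_type`,
#'   `target_type`, `database`, `combined_score`, `n_publications`,
#'   `n_nonhts_methods`.
#' @export
simulate_interactions <- function(study,
                                  n_string = NULL, n_kegg = NULL,
                                  n_mirtarbase = NULL,
                                  score_range = c(0.3, 0.99),
                                  connectivity_enrichment = 3,
                                  seed = 1L) {
  layers <- study$layers
  if (length(layers) == 0) stop("empty feature universe")
  set.seed(seed)
  genes <- unique(layers$mRNA$annotations$gene)
  mets <- layers$metabolite$annotations$node_id
  mirs <- layers$miRNA$annotations$node_id
  n_string <- n_string %||% (3L * length(genes))
  n_kegg <- n_kegg %||% (2L * length(mets))
  n_mirtarbase <- n_mirtarbase %||% (3L * length(mirs))

  wt <- function(ids, active_ids) {
    1 + connectivity_enrichment * (ids %in% active_ids)
  }
  act_gene <- genes[study$truth$active$mRNA[, 1]]
  act_met <- mets[study$truth$active$metabolite[, 1]]
  act_mir <- mirs[study$truth$active$miRNA[, 1]]

  str_a <- sample(genes, n_string, replace = TRUE, prob = wt(genes, act_gene))
  str_b <- sample(genes, n_string, replace = TRUE, prob = wt(genes, act_gene))
  string <- data.table::data.table(
    source_id = pmin(str_a, str_b), target_id = pmax(str_a, str_b),
    source_type = "gene", target_type = "gene", database = "string",
    combined_score = stats::runif(n_string, score_range[1], score_range[2]),
    n_publications = NA_integer_, n_nonhts_methods = NA_integer_)
  string <- string[source_id != target_id]
  string <- unique(string, by = c("source_id", "target_id"))

  kegg <- data.table::data.table(
    source_id = sample(mets, n_kegg, replace = TRUE, prob = wt(mets, act_met)),
    target_id = sample(genes, n_kegg, replace = TRUE,
                       prob = wt(genes, act_gene)),
    source_type = "metabolite", target_type = "gene", database = "kegg",
    combined_score = NA_real_,
    n_publications = NA_integer_, n_nonhts_methods = NA_integer_)
  kegg <- unique(kegg, by = c("source_id", "target_id"))

  mirt <- data.table::data.table(
    source_id = sample(mirs, n_mirtarbase, replace = TRUE,
                       prob = wt(mirs, act_mir)),
    target_id = sample(genes, n_mirtarbase, replace = TRUE,
                       prob = wt(genes, act_gene)),
    source_type = "miRNA", target_type = "gene", database = "mirtarbase",
    combined_score = NA_real_,
    n_publications = 1L + stats::rpois(n_mirtarbase, 1.5),
    n_nonhts_methods = stats::rpois(n_mirtarbase, 1.7))
  mirt <- unique(mirt, by = c("source_id", "target_id"))

  data.table::rbindlist(list(kegg, string, mirt))
}

#' Simulate a gene-set collection
#'
#' Random sets over the mRNA gene universe with sizes clipped to
#' `size_range`; `n_signal` sets are enriched in genes loaded on the planted
#' exposure factor.
#'
#' @param study Output of [simulate_study()].
#' @param n_sets Total number of sets.
#' @param n_signal Number of signal (enriched) sets.
#' @param size_range Allowed set sizes.
#' @param signal_fraction Fraction of a signal set drawn from factor-1-active
#'   genes.
#' @param seed Integer seed.
#' @return Named list of gene-id vectors with attribute `signal` naming the
#'   enriched sets.
#' @export
simulate_genesets <- function(study, n_sets = 50, n_signal = 10,
                              size_range = c(10, 200),
                              signal_fraction = 0.7, seed = 1L) {
  set.seed(seed)
  genes <- study$layers$mRNA$annotations$gene
  act <- genes[study$truth$active$mRNA[, 1]]
  if (max(size_range) > length(genes)) stop("set size exceeds gene universe")
  sizes <- pmin(pmax(round(stats::rlnorm(n_sets, log(40), 0.8)),
                     size_range[1]), size_range[2])
  sets <- vector("list", n_sets)
  names(sets) <- sprintf("SET_%03d", seq_len(n_sets))
  for (i in seq_len(n_sets)) {
    if (i <= n_signal && length(act) > 0) {
      k_act <- min(round(signal_fraction * sizes[i]), length(act))
      sets[[i]] <- unique(c(sample(act, k_act),
                            sample(setdiff(genes, act), sizes[i] - k_act)))
    } else {
      sets[[i]] <- sample(genes, sizes[i])
    }
  }
  attr(sets, "signal") <- names(sets)[seq_len(n_signal)]
  sets
}

#' Construct a signed causal network model
#'
#' @param nodes Character backbone node ids.
#' @param edges data.table with `from`, `to`, `sign` (+1/-1), `weight` (> 0).
#' @param downstream Named list (one entry per backbone node) of data.tables
#'   with `gene` and `sign`; the gene sets must be disjoint and nonempty.
#' @param truth Optional planted-truth list.
#' @return An object of class `causal_network`.
#' @export
causal_network <- function(nodes, edges, downstream, truth = NULL) {
  stopifnot(all(names(downstream) == nodes),
            all(vapply(downstream, nrow, 0L) > 0),
            all(edges$sign %in% c(-1, 1)), all(edges$weight > 0))
  genes <- unlist(lapply(downstream, `[[`, "gene"))
  if (anyDuplicated(genes)) stop("downstream gene sets must be disjoint")
  structure(list(nodes = nodes, edges = edges, downstream = downstream,
                 truth = truth),
            class = "causal_network")
}

#' Simulate a signed causal network model with planted perturbation
#'
#' Builds a connected signed backbone (default 20 nodes) where each backbone
#' node owns a disjoint signed downstream gene set (default 25 genes).
#' Downstream genes are drawn preferentially from exposure-factor-active
#' genes, and downstream signs are aligned with the planted loading signs and
#' a random backbone activity direction, so fold changes from the simulated
#' exposure contrast coherently perturb the network. Backbone edge signs are
#' consistent with the planted activities. The planted direction is emitted
#' as truth.
#'
#' @param study Output of [simulate_study()].
#' @param n_backbone Number of backbone nodes.
#' @param n_downstream Downstream genes per backbone node (disjoint sets).
#' @param extra_edges Backbone edges added beyond the spanning tree.
#' @param seed Integer seed.
#' @return An object of class `causal_network`: `nodes`, `edges`
#'   (data.table `from`, `to`, `sign`, `weight`), `downstream` (named list of
#'   data.tables `gene`, `sign`), `truth` (planted activities).
#' @export
simulate_causal_network <- function(study, n_backbone = 20,
                                    n_downstream = 25, extra_edges = 10,
                                    seed = 1L) {
  set.seed(seed)
  genes <- study$layers$mRNA$annotations$gene
  w1 <- study$truth$loadings$mRNA[, 1]
  need <- n_backbone * n_downstream
  if (need > length(genes)) stop("downstream demand exceeds gene universe")
  act_idx <- which(w1 != 0)
  pool <- c(sample(act_idx), sample(setdiff(seq_along(genes), act_idx)))
  pool <- pool[seq_len(need)]

  activity <- sample(c(-1, 1), n_backbone, replace = TRUE)
  nodes <- sprintf("BB%02d", seq_len(n_backbone))
  downstream <- vector("list", n_backbone)
  names(downstream) <- nodes
  for (i in seq_len(n_backbone)) {
    idx <- pool[((i - 1) * n_downstream + 1):(i * n_downstream)]
    sgn <- ifelse(w1[idx] != 0, activity[i] * sign(w1[idx]),
                  sample(c(-1, 1), length(idx), replace = TRUE))
    downstream[[i]] <- data.table::data.table(gene = genes[idx], sign = sgn)
  }

  # connected signed backbone: random spanning tree plus extra edges
  perm <- sample(n_backbone)
  from <- to <- integer(0)
  for (i in 2:n_backbone) {
    from <- c(from, perm[sample(i - 1, 1)]); to <- c(to, perm[i])
  }
  for (e in seq_len(extra_edges)) {
    pair <- sample(n_backbone, 2)
    from <- c(from, pair[1]); to <- c(to, pair[2])
  }
  edges <- data.table::data.table(from = nodes[pmin(from, to)],
                                  to = nodes[pmax(from, to)])
  edges <- unique(edges[from != to])
  ia <- match(edges$from, nodes); ib <- match(edges$to, nodes)
  edges[, `:=`(sign = activity[ia] * activity[ib], weight = 1)]

  structure(list(nodes = nodes, edges = edges, downstream = downstream,
                 truth = list(activity = stats::setNames(activity, nodes))),
            class = "causal_network")
}

#' Write a synthetic study to TSV files
#'
#' One TSV per modality (features as rows, samples as columns, empty cell =
#' missing), a sample sheet TSV, and the planted truth as JSON.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(study$layers)) {
    lay <- study$layers[[m]]
    dt <- data.table::data.table(feature_id = rownames(lay$mat))
    dt <- cbind(dt, data.table::as.data.table(lay$mat))
    write_tsv(dt, file.path(dir, paste0(m, ".tsv")))
  }
  write_tsv(study$sheet, file.path(dir, "sample_sheet.tsv"))
  truth <- study$truth
  truth$scores <- as.data.frame(truth$scores)
  truth$loadings <- lapply(truth$loadings, as.data.frame)
  truth$active <- lapply(truth$active, as.data.frame)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a causal network model as JSON
#'
#' @param net A `causal_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_causal_network <- function(net, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(nodes = net$nodes, edges = net$edges,
         downstream = lapply(net$downstream, as.data.frame),
         truth = list(activity = as.list(net$truth$activity))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a causal network model from JSON
#'
#' @param path JSON path written by [write_causal_network()].
#' @return A `causal_network` object.
#' @export
read_causal_network <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(nodes = x$nodes,
                 edges = data.table::as.data.table(x$edges),
                 downstream = lapply(x$downstream,
                                     data.table::as.data.table),
                 truth = list(activity = unlist(x$truth$activity))),
            class = "causal_network")
}
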