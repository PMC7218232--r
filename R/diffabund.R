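#' Preprocess one omics layer to the analysis scale
#'
#' Lipid values are divided by the sample's total protein amount (mg) and
#' log2-transformed. Metabolite values missing within measured samples
#' (low-abundance censoring) are imputed as that metabolite's observed
#' minimum, then log2-transformed; samples never measured for the modality
#' stay missing. mRNA, miRNA and protein layers are already log2-scale and
#' pass through unchanged.
#'
#' @param layer An [omics_layer()] on its native scale.
#' @param sheet Sample sheet with `avail_<modality>` flags.
#' @return The preprocessed [omics_layer()].
#' @export
preprocess_layer <- function(layer, sheet) {
  m <- layer$modality
  if (m %in% c("mRNA", "miRNA", "protein")) return(layer)
  mat <- layer$mat
  avail <- sheet[[paste0("avail_", m)]]
  if (is.null(avail)) avail <- rep(TRUE, ncol(mat))
  if (m == "lipid") {
    tp <- layer$total_protein[colnames(mat)]
    if (any(!is.na(mat[, !is.na(tp) & tp <= 0, drop = FALSE]))) {
      stop("zero or negative total protein amount")
    }
    mat <- sweep(mat, 2, tp, `/`)
  } else if (m == "metabolite") {
    obs_cols <- which(avail)
    no_obs <- rowSums(!is.na(mat[, obs_cols, drop = FALSE])) == 0
    if (any(no_obs)) {
      warning(sum(no_obs), " metabolite(s) without any observed value ",
              "dropped: cannot impute")
      mat <- mat[!no_obs, , drop = FALSE]
      layer$annotations <- layer$annotations[!no_obs]
    }
    for (i in seq_len(nrow(mat))) {
      v <- mat[i, obs_cols]
      v[is.na(v)] <- min(v, na.rm = TRUE)
      mat[i, obs_cols] <- v
    }
  }
  bad <- !is.na(mat) & mat <= 0
  if (any(bad)) stop("non-positive values cannot be log2-transformed")
  layer$mat <- log2(mat)
  layer
}

#' Empirical-Bayes prior for feature variances
#'
#' Moment matching on log sample variances: the prior degrees of freedom d0
#' solve `trigamma(d0/2) = var(e) - trigamma(d/2)` (e the adjusted log
#' variances) by monotone Newton iteration, and the prior variance s0^2 comes
#' from the matched mean. When the trigamma target is at or below tolerance,
#' d0 = Inf; exactly equal variances return the common value.
#'
#' @param s2 Vector of residual variances (>= 10 finite positive values).
#' @param d Residual degrees of freedom of each variance (scalar).
#' @param tol Newton tolerance.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `ebayes_prior` with `d0` and `s02`.
#' @export
estimate_prior <- function(s2, d, tol = 1e-8, max_iter = 50) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 10) stop("need at least 10 finite positive variances")
  if (max(s2) - min(s2) == 0) {
    return(ebayes_prior(d0 = Inf, s02 = s2[1]))
  }
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  target <- stats::var(e) - trigamma(d / 2)
  if (target <= tol) {
    return(ebayes_prior(d0 = Inf, s02 = exp(mean(e))))
  }
  # invert trigamma by Newton iteration (monotone decreasing function)
  x <- 0.5 + 1 / target
  for (i in seq_len(max_iter)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / target) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) < tol * x) break
  }
  d0 <- 2 * x
  s02 <- exp(mean(e) + digamma(x) - log(x))
  ebayes_prior(d0 = d0, s02 = s02)
}

#' Construct an empirical-Bayes prior
#'
#' @param d0 Prior degrees of freedom (> = 0; Inf allowed; 0 means no
#'   shrinkage).
#' @param s02 Prior variance (> 0).
#' @return An object of class `ebayes_prior`.
#' @export
ebayes_prior <- function(d0, s02) {
  stopifnot(d0 >= 0, s02 > 0 || d0 == 0)
  structure(list(d0 = d0, s02 = s02), class = "ebayes_prior")
}

#' Posterior (shrunken) variances under an empirical-Bayes prior
#'
#' @param prior An [ebayes_prior()].
#' @param s2 Residual variances.
#' @param d Residual degrees of freedom (scalar or vector).
#' @return Posterior variances `(d0*s02 + d*s2) / (d0 + d)`.
#' @export
posterior_variance <- function(prior, s2, d) {
  if (is.infinite(prior$d0)) return(rep(prior$s02, length(s2)))
  if (prior$d0 == 0) return(s2)
  (prior$d0 * prior$s02 + d * s2) / (prior$d0 + d)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone in rank, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Exposure-vs-Sham moderated-t contrast for one modality
#'
#' Fits, per feature, a two-group equal-variance linear model comparing the
#' exposure arm with the Sham arm at the same time point. Variances are
#' shrunk toward the empirical-Bayes prior, the moderated t gets `d0 + d_g`
#' degrees of freedom, and p-values are BH-adjusted within the
#' (modality, contrast) family. Features missing in more than half of either
#' arm are excluded.
#'
#' @param layer Preprocessed [omics_layer()] (log2 scale).
#' @param sheet Sample sheet.
#' @param group Exposure arm name.
#' @param timepoint Time point.
#' @param prior Optional [ebayes_prior()]; estimated from this contrast's
#'   variances when `NULL`.
#' @param reference Reference arm (default `"Sham"`).
#' @param fdr Significance threshold on the adjusted p-value.
#' @return An object of class `contrast_table`: a data.table with
#'   `feature_id`, `logFC`, `s2`, `df`, `t`, `P.Value`, `adj.P.Val`,
#'   `significant`, plus contrast metadata attributes; or `NULL` with a
#'   warning if either arm has fewer than 2 samples (contrast skipped).
#' @export
fit_contrast <- function(layer, sheet, group, timepoint, prior = NULL,
                         reference = "Sham", fdr = 0.05) {
  avail <- sheet[[paste0("avail_", layer$modality)]]
  in_arm <- function(g) {
    sheet$group == g & sheet$timepoint == timepoint & avail
  }
  c1 <- which(in_arm(group))
  c2 <- which(in_arm(reference))
  if (length(c1) < 2 || length(c2) < 2) {
    warning(sprintf("contrast %s vs %s at %s months skipped: arm with <2 samples",
                    group, reference, timepoint))
    return(NULL)
  }
  X1 <- layer$mat[, sheet$sample_id[c1], drop = FALSE]
  X2 <- layer$mat[, sheet$sample_id[c2], drop = FALSE]
  n1 <- rowSums(!is.na(X1))
  n2 <- rowSums(!is.na(X2))
  keep <- n1 >= pmax(2, ncol(X1) / 2) & n2 >= pmax(2, ncol(X2) / 2)
  if (!all(keep)) {
    message(sum(!keep), " feature(s) excluded from ", layer$modality,
            " contrast (", group, ", ", timepoint,
            " months): missing in >50% of an arm")
  }
  X1 <- X1[keep, , drop = FALSE]; X2 <- X2[keep, , drop = FALSE]
  n1 <- n1[keep]; n2 <- n2[keep]
  m1 <- rowMeans(X1, na.rm = TRUE)
  m2 <- rowMeans(X2, na.rm = TRUE)
  ss1 <- rowSums((X1 - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((X2 - m2)^2, na.rm = TRUE)
  dg <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / dg
  if (is.null(prior)) prior <- estimate_prior(s2, d = max(dg))
  s2post <- posterior_variance(prior, s2, dg)
  beta <- m1 - m2
  tstat <- beta / sqrt(s2post * (1 / n1 + 1 / n2))
  df_total <- prior$d0 + dg
  pval <- 2 * stats::pt(abs(tstat), df = df_total, lower.tail = FALSE)
  adj <- bh_adjust(pval)
  out <- data.table::data.table(
    feature_id = rownames(X1), logFC = beta, s2 = s2, df = dg,
    t = tstat, P.Value = pval, adj.P.Val = adj,
    significant = adj < fdr)
  data.table::setattr(out, "class",
                      c("contrast_table", class(out)))
  data.table::setattr(out, "contrast",
                      list(modality = layer$modality, group = group,
                           timepoint = timepoint, reference = reference,
                           n1 = ncol(X1), n2 = ncol(X2),
                           prior = prior, fdr = fdr))
  out
}

#' Fit all exposure-vs-Sham contrasts of a study
#'
#' @param layers Named list of preprocessed [omics_layer()]s.
#' @param sheet Sample sheet.
#' @param groups Exposure arms to contrast against Sham (defaults to every
#'   non-Sham group present).
#' @param timepoints Time points (defaults to all in the sheet).
#' @param ... Passed to [fit_contrast()].
#' @return Nested list `tables[[modality]][["group@timepoint"]]`, skipped
#'   contrasts omitted.
#' @export
fit_all_contrasts <- function(layers, sheet, groups = NULL,
                              timepoints = NULL, ...) {
  groups <- groups %||% setdiff(unique(sheet$group), "Sham")
  timepoints <- timepoints %||% sort(unique(sheet$timepoint))
  out <- list()
  for (m in names(layers)) {
    out[[m]] <- list()
    for (tp in timepoints) {
      for (g in groups) {
        ct <- withCallingHandlers(
          fit_contrast(layers[[m]], sheet, g, tp, ...),
          warning = function(w) {
            if (grepl("skipped", conditionMessage(w))) {
              invokeRestart("muffleWarning")
            }
          })
        if (!is.null(ct)) out[[m]][[paste0(g, "@", tp)]] <- ct
      }
    }
  }
  out
}

#' Cross-modal fold-change correlation
#'
#' Ordinary least squares of one contrast's log2 fold changes on another's
#' over gene-matched feature pairs; the coefficient of determination
#' summarises how well one molecular layer's response determines the other's.
#'
#' @param a,b [fit_contrast()] tables (e.g. mRNA and protein).
#' @param gene_map_a,gene_map_b data.tables with `feature_id` and `gene`
#'   columns (the layers' annotations).
#' @return List with `r2`, `slope`, `n`.
#' @export
crossmodal_fc_correlation <- function(a, b, gene_map_a, gene_map_b) {
  da <- merge(a[, .(feature_id, logFC)], gene_map_a[, .(feature_id, gene)],
              by = "feature_id")
  db <- merge(b[, .(feature_id, logFC)], gene_map_b[, .(feature_id, gene)],
              by = "feature_id")
  mm <- merge(da[!is.na(gene)], db[!is.na(gene)], by = "gene",
              suffixes = c("_a", "_b"))
  if (nrow(mm) < 3) stop("fewer than 3 gene-matched pairs")
  fit <- stats::lm(logFC_b ~ logFC_a, data = mm)
  list(r2 = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]),
       n = nrow(mm))
}

#' Count significant features per contrast
#'
#' @param tables Nested contrast list from [fit_all_contrasts()].
#' @return data.table with `modality`, `group`, `timepoint`, `n_features`,
#'   `n_significant`.
#' @export
count_significant <- function(tables) {
  rows <- list()
  for (m in names(tables)) {
    for (nm in names(tables[[m]])) {
      ct <- tables[[m]][[nm]]
      meta <- attr(ct, "contrast")
      rows[[length(rows) + 1L]] <- data.table::data.table(
        modality = m, group = meta$group, timepoint = meta$timepoint,
        n_features = nrow(ct), n_significant = sum(ct$significant))
    }
  }
  data.table::rbindlist(rows)
}
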