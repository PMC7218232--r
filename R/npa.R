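#' Backbone differential values from downstream fold changes
#'
#' Each backbone node's differential value is the mean of the signed log2
#' fold changes of its measured downstream genes:
#' `f_i = mean(s_ig * logFC_g)`. Unmeasured genes are excluded; a node with
#' no measured downstream gene gets `f_i = 0` with a warning.
#'
#' @param net A `causal_network` (see [simulate_causal_network()]).
#' @param contrast A [fit_contrast()] table for the mRNA layer, with genes
#'   resolvable via `gene_map`.
#' @param gene_map data.table `feature_id`, `gene` (mRNA annotations).
#' @return Named numeric vector `f` over backbone nodes.
#' @export
backbone_differentials <- function(net, contrast, gene_map) {
  fc <- merge(contrast[, .(feature_id, logFC)],
              gene_map[, .(feature_id, gene)], by = "feature_id")
  fc_by_gene <- stats::setNames(fc$logFC, fc$gene)
  all_genes <- unique(unlist(lapply(net$downstream, `[[`, "gene")))
  if (!any(all_genes %in% names(fc_by_gene))) {
    stop("no overlap between network downstream genes and contrast")
  }
  f <- vapply(net$nodes, function(nd) {
    ds <- net$downstream[[nd]]
    b <- fc_by_gene[ds$gene]
    ok <- !is.na(b)
    if (!any(ok)) return(NA_real_)
    mean(ds$sign[ok] * b[ok])
  }, 0)
  if (anyNA(f)) {
    warning(sum(is.na(f)), " backbone node(s) with no measured downstream ",
            "gene set to 0")
    f[is.na(f)] <- 0
  }
  f
}

# quadratic perturbation amplitude: mean signed-edge disagreement plus mean
# node energy; ia/ib/sgn/wt describe edges in node-index space
npa_quadratic <- function(f, ia, ib, sgn, wt) {
  edge_term <- if (length(ia) > 0) {
    sum(wt * (f[ia] - sgn * f[ib])^2) / length(ia)
  } else 0
  edge_term + sum(f^2) / length(f)
}

#' Quadratic perturbation amplitude of differential values on a backbone
#'
#' @param f Named differential values over backbone nodes.
#' @param edges data.table with `from`, `to`, `sign`, `weight`.
#' @return The amplitude (non-negative scalar).
#' @export
npa_amplitude <- function(f, edges) {
  npa_quadratic(f, match(edges$from, names(f)), match(edges$to, names(f)),
                edges$sign, edges$weight)
}

# degree-preserving double-edge swaps on integer endpoint vectors
rewire_swaps <- function(ia, ib, n_swaps) {
  m <- length(ia)
  if (m < 2) return(list(ia = ia, ib = ib))
  keys <- pmin(ia, ib) * 100000L + pmax(ia, ib)
  pairs <- matrix(sample.int(m, 2 * n_swaps, replace = TRUE), ncol = 2)
  for (s in seq_len(n_swaps)) {
    i <- pairs[s, 1]; j <- pairs[s, 2]
    if (i == j) next
    a <- ia[i]; b <- ib[i]; c <- ia[j]; d <- ib[j]
    if (a == c || a == d || b == c || b == d) next
    k1 <- min(a, d) * 100000L + max(a, d)
    k2 <- min(c, b) * 100000L + max(c, b)
    if (k1 %in% keys || k2 %in% keys) next
    ib[i] <- d; ib[j] <- b
    keys[i] <- k1; keys[j] <- k2
  }
  list(ia = ia, ib = ib)
}

#' Network perturbation amplitude with permutation companions
#'
#' The amplitude is a quadratic form over backbone differential values:
#' the mean signed-edge disagreement `(f_i - s_ij f_j)^2` plus the mean node
#' energy `f_i^2`. Two permutation companion statistics accompany it: `p_O`
#' permutes the assignment of measured genes to downstream sets
#' (upper-tailed: is the amplitude larger than with random downstream gene
#' sets?) and `p_K` rewires the backbone with degree-preserving edge swaps,
#' signs travelling with edges (lower-tailed: are the observed differential
#' values more consistent with the signed topology than with a random
#' topology?). If `layer` and `sheet` are supplied, a 95% confidence
#' interval and a replicate p-value are derived by animal bootstrap of the
#' contrast.
#'
#' @param net A `causal_network`.
#' @param contrast mRNA [fit_contrast()] table.
#' @param gene_map mRNA annotations (`feature_id`, `gene`).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param layer,sheet Optional mRNA layer and sample sheet for the animal
#'   bootstrap (omitted: CI and replicate p are `NA`).
#' @param n_boot Bootstrap replicates.
#' @param alpha Significance level for the flags.
#' @return An object of class `npa_result`: `f`, `npa`, `ci`, `p_replicates`,
#'   `p_O`, `p_K`, and `significant` (all companion statistics below
#'   `alpha`).
#' @export
npa_score <- function(net, contrast, gene_map, n_perm = 500, seed = 1L,
                      layer = NULL, sheet = NULL, n_boot = 200,
                      alpha = 0.05) {
  if (n_perm < 100) stop("n_perm < 100 gives unstable p-values")
  set.seed(seed)
  f <- suppressWarnings(backbone_differentials(net, contrast, gene_map))
  ia <- match(net$edges$from, net$nodes)
  ib <- match(net$edges$to, net$nodes)
  sgn <- net$edges$sign
  wt <- net$edges$weight
  npa <- npa_quadratic(f, ia, ib, sgn, wt)

  # O statistic: permute genes into downstream sets (sizes preserved)
  fc <- merge(contrast[, .(feature_id, logFC)],
              gene_map[, .(feature_id, gene)], by = "feature_id")
  pool <- fc$logFC
  sizes <- vapply(net$downstream, nrow, 0L)
  signs <- unlist(lapply(net$downstream, `[[`, "sign"), use.names = FALSE)
  grp <- rep(seq_along(sizes), sizes)
  null_O <- vapply(seq_len(n_perm), function(i) {
    b <- pool[sample.int(length(pool), sum(sizes))]
    fp <- as.numeric(tapply(signs * b, grp, mean))
    npa_quadratic(fp, ia, ib, sgn, wt)
  }, 0)
  p_O <- (1 + sum(null_O >= npa)) / (n_perm + 1)

  # K statistic: degree-preserving backbone rewiring
  null_K <- vapply(seq_len(n_perm), function(i) {
    rw <- rewire_swaps(ia, ib, n_swaps = 10 * length(ia))
    npa_quadratic(f, rw$ia, rw$ib, sgn, wt)
  }, 0)
  p_K <- (1 + sum(null_K <= npa)) / (n_perm + 1)

  ci <- c(NA_real_, NA_real_); p_rep <- NA_real_
  if (!is.null(layer) && !is.null(sheet)) {
    meta <- attr(contrast, "contrast")
    avail <- sheet[[paste0("avail_", layer$modality)]]
    c1 <- sheet$sample_id[sheet$group == meta$group &
                            sheet$timepoint == meta$timepoint & avail]
    c2 <- sheet$sample_id[sheet$group == meta$reference &
                            sheet$timepoint == meta$timepoint & avail]
    X1 <- layer$mat[, c1, drop = FALSE]
    X2 <- layer$mat[, c2, drop = FALSE]
    boot <- vapply(seq_len(n_boot), function(b) {
      b1 <- X1[, sample.int(ncol(X1), replace = TRUE), drop = FALSE]
      b2 <- X2[, sample.int(ncol(X2), replace = TRUE), drop = FALSE]
      lfc <- rowMeans(b1, na.rm = TRUE) - rowMeans(b2, na.rm = TRUE)
      ctb <- data.table::data.table(feature_id = rownames(X1), logFC = lfc)
      fb <- suppressWarnings(backbone_differentials(net, ctb, gene_map))
      npa_quadratic(fb, ia, ib, sgn, wt)
    }, 0)
    ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
    # bias level: mean amplitude under the downstream-permutation null
    p_rep <- (1 + sum(boot <= mean(null_O))) / (n_boot + 1)
  }
  structure(list(f = f, npa = npa, ci = ci, p_replicates = p_rep,
                 p_O = p_O, p_K = p_K,
                 significant = p_O < alpha && p_K < alpha &&
                   (is.na(p_rep) || p_rep < alpha)),
            class = "npa_result")
}

#' Aggregate network perturbation amplitudes into (relative) biological
#' impact factors
#'
#' Only amplitudes significant in all companion statistics contribute.
#' Within each network, contributing amplitudes are normalised by that
#' network's maximum across contrasts; the per-contrast sums over networks
#' form the BIF, rescaled so the maximally perturbed contrast has RBIF 100.
#'
#' @param results Nested list `results[[network]][[contrast]]` of
#'   [npa_score()] results.
#' @return data.table with `contrast`, `bif`, `rbif`, plus attribute
#'   `status` (`"ok"` or `"all-zero"`).
#' @export
bif_aggregate <- function(results) {
  stopifnot(length(results) >= 1)
  contrasts <- names(results[[1]])
  stopifnot(length(contrasts) >= 1)
  bif <- stats::setNames(numeric(length(contrasts)), contrasts)
  for (net in names(results)) {
    vals <- vapply(contrasts, function(ct) {
      r <- results[[net]][[ct]]
      if (is.null(r) || !isTRUE(r$significant)) 0 else r$npa
    }, 0)
    mx <- max(vals)
    if (mx > 0) bif <- bif + vals / mx
  }
  status <- if (max(bif) > 0) "ok" else "all-zero"
  rbif <- if (max(bif) > 0) 100 * bif / max(bif) else bif
  out <- data.table::data.table(contrast = contrasts, bif = bif, rbif = rbif)
  data.table::setattr(out, "status", status)
  out
}
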