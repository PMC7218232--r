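#' Running-sum enrichment score of one gene set
#'
#' Weighted Kolmogorov-Smirnov running sum with weight exponent 1: genes are
#' ranked by decreasing statistic; set members advance the sum in proportion
#' to their absolute statistic, non-members decrease it by a constant step.
#' The score is the extremum of the running sum (sign kept).
#'
#' @param stat Named statistic vector (no duplicate names).
#' @param set Character vector of gene ids.
#' @return Enrichment score in `[-1, 1]`.
#' @export
enrichment_score <- function(stat, set) {
  ord <- order(-stat, names(stat))
  s <- stat[ord]
  hit <- names(s) %in% set
  nh <- sum(hit)
  if (nh == 0) stop("set has no gene in the universe")
  if (nh == length(s)) stop("set covers the entire universe")
  w <- abs(s) * hit
  sw <- sum(w)
  if (sw == 0) w[hit] <- 1  # all-zero statistics: unweighted steps
  p_hit <- cumsum(w) / max(sw, sum(w[hit]))
  p_miss <- cumsum(!hit) / (length(s) - nh)
  dev <- p_hit - p_miss
  unname(dev[which.max(abs(dev))])
}

#' Preranked gene-set enrichment with a gene-label permutation null
#'
#' For each set, the running-sum enrichment score is compared with scores of
#' random sets of the same size (gene-label permutation). The normalised
#' score divides by the mean absolute null score of matching sign; p-values
#' are two-sided on `|ES|` with the add-one permutation estimator (minimum
#' attainable p is `1/(n_perm+1)`), BH-adjusted across sets. Ties in the
#' ranking statistic are broken by gene id with a warning.
#'
#' @param stat Named ranking statistic (e.g. a factor weight vector).
#' @param sets Named list of gene-id vectors.
#' @param n_perm Number of permutations (>= 1000).
#' @param seed Integer seed.
#' @param min_size,max_size Set-size bounds after intersection with the
#'   universe.
#' @return data.table `set`, `size`, `es`, `nes`, `pval`, `padj`,
#'   `leading_edge` (comma-joined gene ids).
#' @export
gsea_preranked <- function(stat, sets, n_perm = 1000, seed = 1L,
                           min_size = 10, max_size = 500) {
  if (anyDuplicated(names(stat))) stop("duplicate gene ids in the statistic")
  if (n_perm < 1000) stop("n_perm must be >= 1000")
  if (anyDuplicated(stat)) {
    warning("ties in the ranking statistic broken by gene id")
  }
  set.seed(seed)
  ord <- order(-stat, names(stat))
  s <- stat[ord]
  N <- length(s)
  universe <- names(s)
  sets <- lapply(sets, intersect, universe)
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size & sizes < N
  sets <- sets[keep]
  if (length(sets) == 0) stop("no set within the size bounds")
  absw <- abs(s)

  es_for_idx <- function(idx) {
    hit <- logical(N); hit[idx] <- TRUE
    w <- absw * hit
    sw <- sum(w)
    if (sw == 0) { w[hit] <- 1; sw <- sum(w[hit]) }
    dev <- cumsum(w) / sw - cumsum(!hit) / (N - length(idx))
    i <- which.max(abs(dev))
    c(unname(dev[i]), i)
  }

  res <- lapply(names(sets), function(nm) {
    idx <- which(universe %in% sets[[nm]])
    obs <- es_for_idx(idx)
    es <- obs[1]; peak <- obs[2]
    k <- length(idx)
    null_es <- vapply(seq_len(n_perm), function(i) {
      es_for_idx(sample.int(N, k))[1]
    }, 0)
    pval <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
    same_sign <- null_es[sign(null_es) == sign(es)]
    nes <- if (length(same_sign) > 0) es / mean(abs(same_sign)) else NA_real_
    le <- if (es >= 0) {
      universe[intersect(idx, seq_len(peak))]
    } else {
      universe[intersect(idx, peak:N)]
    }
    data.table::data.table(set = nm, size = k, es = es, nes = nes,
                           pval = pval,
                           leading_edge = paste(le, collapse = ","))
  })
  out <- data.table::rbindlist(res)
  out[, padj := bh_adjust(pval)]
  data.table::setorder(out, pval, set)
  data.table::setcolorder(out, c("set", "size", "es", "nes", "pval", "padj",
                                 "leading_edge"))
  out
}

#' Fisher overrepresentation analysis
#'
#' One-sided (enrichment) hypergeometric tail probability per set from the
#' 2x2 selected/set table, BH-adjusted across sets.
#'
#' @param selected Character vector of selected gene ids (subset of the
#'   universe).
#' @param universe Character vector of all gene ids.
#' @param sets Named list of gene-id vectors.
#' @param min_size,max_size Set-size bounds after intersection with the
#'   universe.
#' @return data.table `set`, `size`, `overlap`, `odds_ratio`, `pval`,
#'   `padj`.
#' @export
fisher_ora <- function(selected, universe, sets, min_size = 1,
                       max_size = Inf) {
  if (length(selected) == 0) stop("empty selection")
  if (!all(selected %in% universe)) stop("selected genes outside universe")
  selected <- unique(selected)
  N <- length(unique(universe))
  n <- length(selected)
  sets <- lapply(sets, intersect, universe)
  sizes <- lengths(sets)
  sets <- sets[sizes >= min_size & sizes <= max_size]
  res <- lapply(names(sets), function(nm) {
    K <- length(sets[[nm]])
    k <- length(intersect(selected, sets[[nm]]))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    or <- (k * (N - K - n + k)) / max((K - k) * (n - k), 0.5)
    data.table::data.table(set = nm, size = K, overlap = k,
                           odds_ratio = or, pval = p)
  })
  out <- data.table::rbindlist(res)
  out[, padj := bh_adjust(pval)]
  data.table::setorder(out, pval, set)
  out
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of gene-id vectors.
#' @param path Output path.
#' @param description Optional per-set description (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-set collection from GMT
#'
#' @param path GMT path.
#' @return Named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
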