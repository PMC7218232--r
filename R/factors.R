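#' Fit a multi-omics latent factor model
#'
#' Variational EM for a Gaussian group factor-analysis model with an
#' automatic relevance determination (ARD) prior per (modality, factor):
#' each modality's feature-by-sample matrix is decomposed as
#' `Y_m = W_m %*% t(Z) + noise`, with a shared sample-score matrix `Z` and
#' modality-specific weights `W_m`. Samples absent from a modality contribute
#' nothing to that modality's updates, so whole missing sample/modality
#' blocks are handled natively. Each modality is centered per feature and
#' scaled to equal total variance so no layer dominates. Factors explaining
#' less than `drop_threshold` variance in every modality are dropped at
#' convergence, the rest are ordered by total variance explained, and each
#' factor's sign is fixed so its largest-magnitude weight is positive.
#'
#' The evidence lower bound (ELBO) is tracked every iteration and is
#' non-decreasing (coordinate-ascent updates with exact noise/ARD precision
#' maximisation).
#'
#' @param layers Named list of preprocessed [omics_layer()]s (log2 scale).
#' @param sheet Optional sample sheet (unused in the updates; samples are
#'   taken from the matrices' columns).
#' @param k_init Initial number of factors.
#' @param tol Relative ELBO convergence tolerance.
#' @param max_iter Maximum number of variational EM iterations.
#' @param drop_threshold Variance-explained threshold below which a factor is
#'   dropped (fraction, default 0.001 = 0.1%).
#' @param seed Integer seed (used only to disambiguate a rank-deficient
#'   initialisation; the fit is deterministic given data and seed).
#' @return An object of class `factor_model` with scores `Z`, per-modality
#'   weights `W`, ARD precisions `alpha`, noise precisions `tau`,
#'   variance-explained matrix `r2`, and the ELBO trajectory `elbo`.
#' @export
fit_mofa <- function(layers, sheet = NULL, k_init = 10, tol = 1e-6,
                     max_iter = 300, drop_threshold = 0.001, seed = 1L) {
  if (length(layers) < 2) stop("need at least 2 modalities")
  Y <- lapply(layers, function(l) l$mat)
  N <- ncol(Y[[1]])
  samples <- colnames(Y[[1]])
  for (m in names(Y)) {
    if (!identical(colnames(Y[[m]]), samples)) {
      Y[[m]] <- Y[[m]][, samples, drop = FALSE]
    }
  }
  K <- k_init
  if (K > min(N, vapply(Y, nrow, 0L))) stop("k_init exceeds a data dimension")
  obs_any <- Reduce(`|`, lapply(Y, function(y) colSums(!is.na(y)) > 0))
  if (!any(obs_any)) stop("no overlapping samples between modalities")

  # center per feature, scale each modality to equal total variance
  center <- list(); scale_f <- numeric(length(Y)); names(scale_f) <- names(Y)
  for (m in names(Y)) {
    mu <- rowMeans(Y[[m]], na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    Y[[m]] <- Y[[m]] - mu
    v <- sum(apply(Y[[m]], 1, stats::var, na.rm = TRUE), na.rm = TRUE)
    if (v <= 0) stop("modality ", m, " has no variance / all-missing entries")
    scale_f[m] <- sqrt(100 / v)
    Y[[m]] <- Y[[m]] * scale_f[m]
    center[[m]] <- mu
  }

  M <- lapply(Y, function(y) !is.na(y))
  Y0 <- lapply(Y, function(y) { y[is.na(y)] <- 0; y })
  ysq <- vapply(Y0, function(y) sum(y^2), 0)
  nobs <- vapply(M, sum, 0)

  # mask-pattern groups per modality (feature rows sharing an observation
  # pattern share their weight posterior covariance)
  pat <- lapply(M, function(mm) {
    key <- apply(mm, 1, function(r) paste(which(r), collapse = ","))
    split(seq_len(nrow(mm)), key)
  })
  pat_cols <- lapply(names(Y), function(m) {
    lapply(pat[[m]], function(rows) M[[m]][rows[1], ])
  })
  names(pat_cols) <- names(Y)

  # deterministic initialisation: right singular vectors of the stacked data
  X <- do.call(rbind, Y0)
  sv <- svd(X, nu = 0, nv = K)
  muZ <- sv$v
  rank_ok <- sv$d[seq_len(K)] > 1e-8 * sv$d[1]
  set.seed(seed)
  if (any(!rank_ok)) {
    muZ[, !rank_ok] <- matrix(stats::rnorm(N * sum(!rank_ok)), N)
  }
  # fix sign: largest-|entry| positive (keeps permutation equivariance)
  for (k in seq_len(K)) {
    i <- which.max(abs(muZ[, k]))
    if (muZ[i, k] < 0) muZ[, k] <- -muZ[, k]
  }
  muZ <- muZ * sqrt(N)
  Sz <- replicate(N, diag(K), simplify = FALSE)
  alpha <- lapply(Y, function(y) rep(1, K))
  tau <- vapply(Y, function(y) 1, 0)
  muW <- lapply(Y, function(y) matrix(0, nrow(y), K))
  Sw <- lapply(pat, function(p) lapply(p, function(rows) diag(K)))

  elbo <- numeric(0)
  eyeK <- diag(K)
  for (iter in seq_len(max_iter)) {
    # --- update q(W) ---
    Ezz <- lapply(seq_len(N), function(n) {
      Sz[[n]] + tcrossprod(muZ[n, ])
    })
    for (m in names(Y)) {
      for (pn in names(pat[[m]])) {
        rows <- pat[[m]][[pn]]
        cols <- pat_cols[[m]][[pn]]
        EzzSum <- Reduce(`+`, Ezz[cols], matrix(0, K, K))
        Swp <- solve(diag(alpha[[m]], K) + tau[[m]] * EzzSum)
        Sw[[m]][[pn]] <- (Swp + t(Swp)) / 2
        muW[[m]][rows, ] <-
          tau[[m]] * (Y0[[m]][rows, cols, drop = FALSE] %*%
                        muZ[cols, , drop = FALSE]) %*% Sw[[m]][[pn]]
      }
    }
    # --- update q(Z) ---
    # B_n (precision contribution) shared by samples with equal availability
    Xp <- lapply(names(Y), function(m) {
      lapply(names(pat[[m]]), function(pn) {
        rows <- pat[[m]][[pn]]
        length(rows) * Sw[[m]][[pn]] +
          crossprod(muW[[m]][rows, , drop = FALSE])
      })
    })
    names(Xp) <- names(Y)
    sig_key <- vapply(seq_len(N), function(n) {
      paste(unlist(lapply(names(Y), function(m) {
        vapply(pat_cols[[m]], function(pc) pc[n], TRUE)
      })), collapse = "")
    }, "")
    RHS <- Reduce(`+`, lapply(names(Y), function(m) {
      tau[[m]] * crossprod(Y0[[m]], muW[[m]])
    }))
    for (key in unique(sig_key)) {
      ns <- which(sig_key == key)
      n0 <- ns[1]
      B <- matrix(0, K, K)
      for (m in names(Y)) {
        for (j in seq_along(pat[[m]])) {
          if (pat_cols[[m]][[j]][n0]) B <- B + tau[[m]] * Xp[[m]][[j]]
        }
      }
      Szk <- solve(eyeK + B)
      Szk <- (Szk + t(Szk)) / 2
      for (n in ns) Sz[[n]] <- Szk
      muZ[ns, ] <- RHS[ns, , drop = FALSE] %*% Szk
    }
    Ezz <- lapply(seq_len(N), function(n) Sz[[n]] + tcrossprod(muZ[n, ]))

    # --- point updates: ARD and noise precisions ---
    for (m in names(Y)) {
      eww_diag <- rep(0, K)
      for (pn in names(pat[[m]])) {
        eww_diag <- eww_diag +
          length(pat[[m]][[pn]]) * diag(Sw[[m]][[pn]])
      }
      eww_diag <- eww_diag + colSums(muW[[m]]^2)
      alpha[[m]] <- pmin(nrow(Y[[m]]) / pmax(eww_diag, 1e-300), 1e10)
    }
    resid <- numeric(length(Y)); names(resid) <- names(Y)
    for (m in names(Y)) {
      term2 <- sum(Y0[[m]] * (muW[[m]] %*% t(muZ)))
      term3 <- 0
      for (j in seq_along(pat[[m]])) {
        cols <- which(pat_cols[[m]][[j]])
        EzzSum <- Reduce(`+`, Ezz[cols], matrix(0, K, K))
        term3 <- term3 + sum(Xp[[m]][[j]] * EzzSum)
      }
      resid[m] <- max(ysq[m] - 2 * term2 + term3, 1e-10 * nobs[m])
      tau[[m]] <- nobs[m] / resid[m]
    }

    # --- ELBO ---
    ll <- sum(vapply(names(Y), function(m) {
      0.5 * nobs[m] * (log(tau[[m]]) - log(2 * pi)) -
        0.5 * tau[[m]] * resid[m]
    }, 0))
    klw <- 0
    for (m in names(Y)) {
      la <- log(alpha[[m]])
      for (pn in names(pat[[m]])) {
        rows <- pat[[m]][[pn]]
        np <- length(rows)
        eww <- np * diag(Sw[[m]][[pn]]) +
          colSums(muW[[m]][rows, , drop = FALSE]^2)
        klw <- klw + 0.5 * (sum(alpha[[m]] * eww) - np * K -
                              np * determinant(Sw[[m]][[pn]])$modulus[1] -
                              np * sum(la))
      }
    }
    klz <- 0
    for (key in unique(sig_key)) {
      ns <- which(sig_key == key)
      ld <- determinant(Sz[[ns[1]]])$modulus[1]
      klz <- klz + 0.5 * (length(ns) * (sum(diag(Sz[[ns[1]]])) - K - ld) +
                            sum(muZ[ns, , drop = FALSE]^2))
    }
    elbo <- c(elbo, ll - klw - klz)
    if (iter >= 2) {
      d <- elbo[iter] - elbo[iter - 1]
      if (abs(d) < tol * abs(elbo[iter])) break
    }
  }

  model <- structure(
    list(Z = muZ, W = muW, alpha = alpha, tau = tau, elbo = elbo,
         data = Y, masks = M, samples = samples, center = center,
         scale = scale_f, seed = seed),
    class = "factor_model")
  model <- finalize_factors(model, drop_threshold)
  model
}

# drop weak factors, order by variance explained, fix signs; dropping uses
# incremental (sequential-residual) variance so redundant copies of one
# direction do not survive on shared variance
finalize_factors <- function(model, drop_threshold) {
  # absorb (numerically) collinear factors into their partner before the
  # variance bookkeeping: exact low-rank data can split one direction over
  # several factors
  K0 <- ncol(model$Z)
  if (K0 > 1) {
    sds <- apply(model$Z, 2, stats::sd)
    for (j in seq_len(K0)) {
      for (k in seq_len(K0)) {
        if (j == k || sds[j] == 0 || sds[k] == 0) next
        if (abs(stats::cor(model$Z[, j], model$Z[, k])) > 0.999 &&
              sds[j] <= sds[k]) {
          cc <- sum(model$Z[, j] * model$Z[, k]) / sum(model$Z[, k]^2)
          for (m in names(model$W)) {
            model$W[[m]][, k] <- model$W[[m]][, k] + cc * model$W[[m]][, j]
            model$W[[m]][, j] <- 0
          }
          model$Z[, j] <- 0
          sds[j] <- 0
        }
      }
    }
  }
  r2 <- variance_explained_matrix(model)
  ord0 <- order(-colSums(r2))
  res <- model$data
  ss_tot <- vapply(names(res), function(m) sum(res[[m]][model$masks[[m]]]^2),
                   0)
  keep_inc <- logical(ncol(r2))
  for (k in ord0) {
    inc <- vapply(names(res), function(m) {
      fit <- tcrossprod(model$W[[m]][, k], model$Z[, k])
      (sum(res[[m]][model$masks[[m]]]^2) -
         sum((res[[m]] - fit)[model$masks[[m]]]^2)) / ss_tot[m]
    }, 0)
    if (max(inc) >= drop_threshold) {
      keep_inc[k] <- TRUE
      for (m in names(res)) {
        res[[m]] <- res[[m]] - tcrossprod(model$W[[m]][, k], model$Z[, k])
      }
    }
  }
  keep <- which(keep_inc)
  if (length(keep) == 0) keep <- which.max(apply(r2, 2, max))
  ord <- keep[order(-colSums(r2[, keep, drop = FALSE]))]
  model$Z <- model$Z[, ord, drop = FALSE]
  model$W <- lapply(model$W, function(w) w[, ord, drop = FALSE])
  model$alpha <- lapply(model$alpha, function(a) a[ord])
  model$r2 <- r2[, ord, drop = FALSE]
  K <- length(ord)
  colnames(model$Z) <- paste0("factor", seq_len(K))
  colnames(model$r2) <- paste0("factor", seq_len(K))
  rownames(model$Z) <- model$samples
  for (k in seq_len(K)) {
    allw <- unlist(lapply(model$W, function(w) w[, k]))
    if (allw[which.max(abs(allw))] < 0) {
      model$Z[, k] <- -model$Z[, k]
      model$W <- lapply(model$W, function(w) { w[, k] <- -w[, k]; w })
    }
  }
  for (m in names(model$W)) {
    colnames(model$W[[m]]) <- paste0("factor", seq_len(K))
    rownames(model$W[[m]]) <- rownames(model$data[[m]])
  }
  model
}

variance_explained_matrix <- function(model) {
  K <- ncol(model$Z)
  mods <- names(model$data)
  r2 <- matrix(0, length(mods), K,
               dimnames = list(mods, paste0("factor", seq_len(K))))
  for (m in mods) {
    Y <- model$data[[m]]; Mk <- model$masks[[m]]
    ss_tot <- sum(Y[Mk]^2)
    for (k in seq_len(K)) {
      fit <- tcrossprod(model$W[[m]][, k], model$Z[, k])
      r2[m, k] <- max(0, 1 - sum((Y - fit)[Mk]^2) / ss_tot)
    }
  }
  r2
}

#' Variance explained per modality and factor
#'
#' `R^2_{m,k} = 1 - SS(Y_m - z_k w_mk^T) / SS(Y_m)` over observed entries of
#' the centered, scaled data, clipped at 0, plus the total per modality from
#' the full reconstruction.
#'
#' @param model A [fit_mofa()] model.
#' @return data.table with `modality`, `factor`, `r2`, and per-modality
#'   `total` rows (factor = "total").
#' @export
variance_explained <- function(model) {
  r2 <- variance_explained_matrix(model)
  out <- data.table::as.data.table(as.table(r2))
  data.table::setnames(out, c("modality", "factor", "r2"))
  out[, factor := as.character(factor)]
  tot <- data.table::data.table(
    modality = names(model$data),
    factor = "total",
    r2 = vapply(names(model$data), function(m) {
      Y <- model$data[[m]]; Mk <- model$masks[[m]]
      fit <- model$W[[m]] %*% t(model$Z)
      max(0, 1 - sum((Y - fit)[Mk]^2) / sum(Y[Mk]^2))
    }, 0))
  data.table::rbindlist(list(out, tot))
}

#' Sparse generalized canonical correlation (block sparse PLS, canonical mode)
#'
#' Alternating outer-iteration over modalities with a fully connected design:
#' each modality's loading is updated toward the sum of the other blocks'
#' scores, hard-thresholded to its `keep` largest absolute entries (ties
#' broken by feature index), and renormalised to unit norm. Components are
#' extracted sequentially with canonical-mode deflation (each block deflated
#' by its own score). Samples missing any included modality are dropped.
#'
#' @param layers Named list of preprocessed [omics_layer()]s.
#' @param keep Number of nonzero loading entries per modality per component
#'   (scalar or named vector).
#' @param ncomp Number of components.
#' @param tol Convergence tolerance on loading change.
#' @param max_iter Maximum alternating iterations per component.
#' @param seed Unused (the fit is deterministic); kept for interface
#'   stability.
#' @return An object of class `sgcca_model` with per-modality `loadings`
#'   (features x ncomp), `scores` (samples x ncomp), and the retained
#'   complete-case sample ids.
#' @export
fit_sgcca <- function(layers, keep = 30, ncomp = 2, tol = 1e-6,
                      max_iter = 200, seed = 1L) {
  mods <- names(layers)
  if (length(keep) == 1) keep <- stats::setNames(rep(keep, length(mods)), mods)
  complete <- Reduce(`&`, lapply(layers, function(l) {
    colSums(is.na(l$mat)) == 0
  }))
  n_drop <- sum(!complete)
  if (n_drop > 0) {
    message(n_drop, " sample(s) dropped for sGCCA (incomplete across ",
            "modalities)")
  }
  if (sum(complete) < 3) stop("fewer than 3 complete-case samples")
  X <- lapply(layers, function(l) {
    x <- t(l$mat[, complete, drop = FALSE])
    x <- scale(x)
    x[, attr(x, "scaled:scale") == 0] <- 0
    x
  })
  for (m in mods) {
    if (keep[[m]] > ncol(X[[m]])) stop("keep exceeds feature count in ", m)
  }
  nsamp <- sum(complete)
  loadings <- lapply(X, function(x) {
    matrix(0, ncol(x), ncomp, dimnames = list(colnames(x), NULL))
  })
  scores <- lapply(X, function(x) matrix(0, nsamp, ncomp))

  hard_threshold <- function(v, k) {
    if (k < length(v)) {
      ord <- order(-abs(v), seq_along(v))
      v[-ord[seq_len(k)]] <- 0
    }
    v
  }
  for (comp in seq_len(ncomp)) {
    a <- lapply(mods, function(m) {
      sv <- svd(X[[m]], nu = 0, nv = 1)$v[, 1]
      i <- which.max(abs(sv))
      if (sv[i] < 0) sv <- -sv
      av <- hard_threshold(sv, keep[[m]])
      av / sqrt(sum(av^2))
    })
    names(a) <- mods
    for (it in seq_len(max_iter)) {
      delta <- 0
      for (m in mods) {
        tsum <- rowSums(vapply(setdiff(mods, m), function(m2) {
          drop(X[[m2]] %*% a[[m2]])
        }, numeric(nsamp)))
        v <- drop(crossprod(X[[m]], tsum))
        v <- hard_threshold(v, keep[[m]])
        nv <- sqrt(sum(v^2))
        if (nv == 0) v[1] <- 1 else v <- v / nv
        delta <- max(delta, max(abs(v - a[[m]])))
        a[[m]] <- v
      }
      if (delta < tol) break
    }
    for (m in mods) {
      loadings[[m]][, comp] <- a[[m]]
      t_m <- drop(X[[m]] %*% a[[m]])
      scores[[m]][, comp] <- t_m
      denom <- sum(t_m^2)
      if (denom > 0) {
        X[[m]] <- X[[m]] - t_m %*% (crossprod(t_m, X[[m]]) / denom)
      }
    }
  }
  structure(list(loadings = loadings, scores = scores, keep = keep,
                 samples = colnames(layers[[1]]$mat)[complete],
                 n_dropped = n_drop),
            class = "sgcca_model")
}

#' Principal component analysis of one layer
#'
#' Columns never measured are dropped; remaining missing entries are
#' mean-imputed per feature for the PCA only.
#'
#' @param layer A preprocessed [omics_layer()].
#' @return List with `scores` (samples x PC), `percent_var`, and the sample
#'   ids used.
#' @export
pca_layer <- function(layer) {
  mat <- layer$mat
  use <- colSums(!is.na(mat)) > 0
  if (sum(use) < 2) stop("fewer than 2 measured samples")
  X <- mat[, use, drop = FALSE]
  for (i in seq_len(nrow(X))) {
    na <- is.na(X[i, ])
    if (any(na)) X[i, na] <- mean(X[i, !na])
  }
  pc <- stats::prcomp(t(X), center = TRUE, scale. = FALSE)
  pv <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, percent_var = pv, samples = colnames(X))
}

#' Correlate group-mean factor scores with a sample covariate
#'
#' Per-(group, time point) mean factor scores are regressed (OLS) on the
#' per-cell mean of the covariate (e.g. the BALF total immune cell count).
#'
#' @param model A [fit_mofa()] model.
#' @param sheet Sample sheet containing the covariate.
#' @param covariate Covariate column name.
#' @param factor Factor index (default 1).
#' @return List with `r2`, `slope`, and the per-cell `means` table.
#' @export
correlate_factor_covariate <- function(model, sheet,
                                       covariate = "balf_total_cells",
                                       factor = 1) {
  sc <- data.table::data.table(sample_id = rownames(model$Z),
                               score = model$Z[, factor])
  dt <- merge(sc, sheet, by = "sample_id")
  cells <- dt[!is.na(get(covariate)),
              .(mean_score = mean(score),
                mean_cov = mean(get(covariate))),
              by = .(group, timepoint)]
  if (nrow(cells) < 3) stop("fewer than 3 group x timepoint cells")
  fit <- stats::lm(mean_score ~ mean_cov, data = cells)
  list(r2 = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]),
       means = cells)
}
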