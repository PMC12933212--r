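# SIMPLS for a single response (de Jong 1993). X must be column-centred;
# y is centred internally. Components are deterministic for univariate y:
# each score direction is the current (deflated) covariance vector X'y, so
# every component has non-negative covariance with the outcome and no sign
# ambiguity arises.
simpls_core <- function(Xc, y, ncomp, tol = 1e-12) {
  n <- nrow(Xc); V <- ncol(Xc)
  y0 <- y - mean(y)
  S <- crossprod(Xc, y0)
  R <- matrix(0, V, ncomp)
  Q <- numeric(ncomp)
  TT <- matrix(0, n, ncomp)
  Vb <- matrix(0, V, ncomp)
  used <- 0L
  for (a in seq_len(ncomp)) {
    if (sqrt(sum(S^2)) < tol) break
    r <- S
    t <- Xc %*% r
    nt <- sqrt(sum(t^2))
    if (nt < tol) break
    t <- t / nt
    r <- r / nt
    p <- crossprod(Xc, t)
    v <- p
    if (a > 1) {
      Vprev <- Vb[, seq_len(a - 1), drop = FALSE]
      v <- v - Vprev %*% crossprod(Vprev, p)
    }
    nv <- sqrt(sum(v^2))
    if (nv < tol) break
    v <- v / nv
    Vb[, a] <- v
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r
    Q[a] <- sum(y0 * t)
    TT[, a] <- t
    used <- a
  }
  if (used == 0L) {
    return(list(coef = numeric(V), fitted = rep(mean(y), n), r2 = 0,
                ncomp_used = 0L))
  }
  ks <- seq_len(used)
  coef <- drop(R[, ks, drop = FALSE] %*% Q[ks])
  fitted <- drop(TT[, ks, drop = FALSE] %*% Q[ks]) + mean(y)
  r2 <- 1 - sum((y - fitted)^2) / sum(y0^2)
  list(coef = coef, fitted = fitted, r2 = r2, ncomp_used = used)
}

feature_matrix <- function(X) {
  if (inherits(X, "dtlvc_features")) X$X else as.matrix(X)
}

check_plsr_inputs <- function(X, y, n_components) {
  if (nrow(X) != length(y)) stopf("length of y (%d) does not match rows of X (%d)",
                                  length(y), nrow(X))
  if (nrow(X) < 3) stopf("need at least 3 subjects")
  if (var(y) == 0) stopf("outcome is constant; lesion-symptom model is undefined")
  max_comp <- min(nrow(X) - 1L, ncol(X))
  if (n_components < 1 || n_components > max_comp) {
    stopf("n_components must be in [1, %d] for %d subjects and %d voxels",
          max_comp, nrow(X), ncol(X))
  }
  invisible(TRUE)
}

#' Fit a PLSR lesion-symptom model
#'
#' Fits partial least squares regression of a behavioural outcome on the
#' DTLVC-normalized lesion features, using the SIMPLS algorithm for a single
#' response. The back-projected regression coefficients form the voxel
#' weight map: a positive weight means damage at that voxel is associated
#' with an increased outcome. Features are column-centred before fitting
#' (set `standardize = TRUE` to also scale columns to unit variance).
#'
#' @param features A `dtlvc_features` object (or plain numeric matrix,
#'   subjects in rows).
#' @param y Numeric outcome vector aligned to the feature rows.
#' @param n_components Number of latent components to retain.
#' @param standardize Scale feature columns to unit variance (default FALSE;
#'   DTLVC features are left on their natural scale).
#' @return A list with `weight_map` (per-voxel coefficients over the feature
#'   columns), `fitted`, `r2` (in-sample fraction of variance explained),
#'   `n_components` (as used; deflation stops early if the covariance with
#'   the outcome is exhausted).
#' @export
fit_plsr <- function(features, y, n_components = 1, standardize = FALSE) {
  X <- feature_matrix(features)
  y <- as.numeric(y)
  check_plsr_inputs(X, y, n_components)
  Xc <- scale(X, center = TRUE, scale = standardize)
  Xc[is.na(Xc)] <- 0  # zero-variance columns under standardization
  f <- simpls_core(Xc, y, n_components)
  list(weight_map = f$coef, fitted = f$fitted, r2 = f$r2,
       n_components = f$ncomp_used)
}

#' Choose the number of PLSR components by cross-validation
#'
#' Evaluates candidate component counts by 5-fold cross-validated predictive
#' R-squared (1 - PRESS / total sum of squares, pooled over folds) and
#' returns the best candidate; if no candidate predicts better than the
#' outcome mean (all CV R-squared <= 0), falls back to 1 component.
#'
#' @inheritParams fit_plsr
#' @param max_components Largest candidate (capped by fold size and voxel
#'   count).
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed for the fold assignment.
#' @return Integer component count, with attribute `cv_r2` giving the
#'   per-candidate CV R-squared.
#' @export
select_n_components <- function(features, y, max_components = 10, folds = 5,
                                seed = 1, standardize = FALSE) {
  X <- feature_matrix(features)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < folds + 1) stopf("need more than `folds` subjects")
  kmax <- min(max_components, n - ceiling(n / folds) - 1L, ncol(X))
  kmax <- max(kmax, 1L)
  fold_id <- withr::with_seed(derive_seed(seed, 3L),
                              sample(rep_len(seq_len(folds), n)))
  press <- numeric(kmax)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    Xtr <- X[!test, , drop = FALSE]
    ytr <- y[!test]
    if (var(ytr) == 0) next
    ctr <- colMeans(Xtr)
    Xtrc <- sweep(Xtr, 2, ctr)
    sc <- rep(1, ncol(X))
    if (standardize) {
      sc <- apply(Xtr, 2, sd)
      sc[sc == 0] <- 1
      Xtrc <- sweep(Xtrc, 2, sc, "/")
    }
    Xtec <- sweep(sweep(X[test, , drop = FALSE], 2, ctr), 2, sc, "/")
    for (k in seq_len(kmax)) {
      fit <- simpls_core(Xtrc, ytr, k)
      pred <- drop(Xtec %*% fit$coef) + mean(ytr)
      press[k] <- press[k] + sum((y[test] - pred)^2)
    }
  }
  cv_r2 <- 1 - press / sum((y - mean(y))^2)
  best <- which.max(cv_r2)
  if (cv_r2[best] <= 0) best <- 1L
  structure(as.integer(best), cv_r2 = cv_r2)
}

#' Permutation test of the whole-map PLSR fit
#'
#' Tests the significance of the entire lesion-symptom map in a single test:
#' the outcome is randomly permuted across subjects `n_permutations` times,
#' the full PLSR model is refit each time, and the p-value is the add-one
#' permutation estimate `(1 + #\{null R2 >= observed R2\}) / (B + 1)`, which
#' can never be zero.
#'
#' @inheritParams fit_plsr
#' @param n_permutations Number of permutations (default 1000).
#' @param seed Integer seed (the permutation stream is independent of the
#'   bootstrap stream for the same master seed).
#' @return A list with `perm_p`, `observed_r2`, `null_r2` (length
#'   `n_permutations`).
#' @export
permute_model_fit <- function(features, y, n_components = 1,
                              n_permutations = 1000, seed = 1,
                              standardize = FALSE) {
  X <- feature_matrix(features)
  y <- as.numeric(y)
  check_plsr_inputs(X, y, n_components)
  Xc <- scale(X, center = TRUE, scale = standardize)
  Xc[is.na(Xc)] <- 0
  obs <- simpls_core(Xc, y, n_components)$r2
  null_r2 <- withr::with_seed(derive_seed(seed, 1L), {
    vapply(seq_len(n_permutations), function(b) {
      simpls_core(Xc, sample(y), n_components)$r2
    }, numeric(1))
  })
  list(perm_p = perm_pvalue(null_r2, obs), observed_r2 = obs,
       null_r2 = null_r2)
}

#' Bootstrap voxel-wise z-statistics and model-fit confidence interval
#'
#' Resamples subjects with replacement `n_bootstrap` times, refits the PLSR
#' model on each resample, and returns (i) the voxel z-map — each observed
#' weight divided by its bootstrap standard deviation — and (ii) the
#' percentile 95% confidence interval of the in-sample R-squared. Voxels
#' whose weight has zero bootstrap variance get z = 0 and are flagged rather
#' than producing infinities. Resamples with a constant outcome (possible in
#' small cohorts) are redrawn.
#'
#' @inheritParams fit_plsr
#' @param n_bootstrap Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param conf_level Confidence level for the R-squared interval.
#' @return A list with `z_map`, `r2_ci` (length 2), `boot_r2`, `weight_sd`,
#'   `zero_variance` (logical per voxel).
#' @export
bootstrap_voxel_stats <- function(features, y, n_components = 1,
                                  n_bootstrap = 1000, seed = 1,
                                  standardize = FALSE, conf_level = 0.95) {
  X <- feature_matrix(features)
  y <- as.numeric(y)
  check_plsr_inputs(X, y, n_components)
  if (n_bootstrap < 2) stopf("need at least 2 bootstrap resamples")
  Xc <- scale(X, center = TRUE, scale = standardize)
  Xc[is.na(Xc)] <- 0
  obs <- simpls_core(Xc, y, n_components)
  n <- nrow(X); V <- ncol(X)
  # streaming mean and sum of squares keeps memory at O(V)
  wsum <- numeric(V); wsum2 <- numeric(V)
  boot_r2 <- numeric(n_bootstrap)
  withr::with_seed(derive_seed(seed, 2L), {
    for (b in seq_len(n_bootstrap)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (var(y[idx]) > 0) break
      }
      Xb <- scale(X[idx, , drop = FALSE], center = TRUE, scale = standardize)
      Xb[is.na(Xb)] <- 0
      fb <- simpls_core(Xb, y[idx], n_components)
      wsum <- wsum + fb$coef
      wsum2 <- wsum2 + fb$coef^2
      boot_r2[b] <- fb$r2
    }
  })
  wvar <- pmax(wsum2 / n_bootstrap - (wsum / n_bootstrap)^2, 0) *
    n_bootstrap / (n_bootstrap - 1)
  wsd <- sqrt(wvar)
  zero_var <- wsd <= .Machine$double.eps^0.5 * max(wsd, 1e-300)
  z <- ifelse(zero_var, 0, obs$coef / ifelse(zero_var, 1, wsd))
  alpha <- 1 - conf_level
  list(z_map = z,
       r2_ci = unname(quantile(boot_r2, c(alpha / 2, 1 - alpha / 2))),
       boot_r2 = boot_r2, weight_sd = wsd, zero_variance = zero_var)
}

#' Family-wise error corrected voxel threshold for a z-map
#'
#' Converts bootstrap z-statistics to two-sided p-values under the standard
#' normal approximation and applies Holm-Bonferroni control of the
#' family-wise error rate across all analysis-mask voxels. An empty survivor
#' set is a legitimate outcome.
#'
#' @param z_map Numeric vector of voxel z-statistics.
#' @param alpha_fwe Family-wise error level (default 0.05).
#' @return Logical vector marking surviving voxels, with attribute `p_holm`
#'   (the adjusted p-values).
#' @export
fwe_voxel_threshold <- function(z_map, alpha_fwe = 0.05) {
  p <- 2 * pnorm(-abs(z_map))
  p_adj <- p.adjust(p, method = "holm")
  structure(p_adj <= alpha_fwe, p_holm = p_adj)
}
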