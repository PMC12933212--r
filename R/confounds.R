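#' Simple linear regression of an outcome on one covariate
#'
#' Pearson correlation with a two-sided t-test on n - 2 degrees of freedom,
#' the standard confound screen. Missing values are dropped pairwise, so
#' each covariate analysis uses its own n.
#'
#' @param x Covariate vector.
#' @param y Outcome vector, same length.
#' @param analysis Optional label recorded in the output.
#' @return A one-row tibble: `analysis`, `n`, `r`, `p`.
#' @export
simple_regression <- function(x, y, analysis = NA_character_) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stopf("need at least 3 complete pairs (got %d)", length(x))
  if (sd(x) == 0 || sd(y) == 0) {
    stopf("correlation undefined: zero-variance input")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(analysis = analysis, n = length(x),
                 r = unname(ct$estimate), p = ct$p.value)
}

#' Remove the variance of a covariate from an outcome
#'
#' Ordinary least-squares residualization of `y` on an intercept and `c`,
#' used to re-run the mapping analysis with depression severity (BDI-II
#' total minus the appetite item) regressed out of the appetite score. The
#' residuals have zero mean and zero correlation with the covariate, and
#' re-residualizing on the same covariate changes nothing.
#'
#' @param y Outcome vector.
#' @param covariate Covariate vector, same length. A constant covariate
#'   yields the centred outcome, with attribute `constant_covariate = TRUE`.
#' @return Numeric residual vector (NA where either input is NA).
#' @export
residualize <- function(y, covariate) {
  if (length(y) != length(covariate)) stopf("y and covariate must have equal length")
  ok <- complete.cases(y, covariate)
  if (sum(ok) < 3) stopf("need at least 3 complete pairs")
  out <- rep(NA_real_, length(y))
  if (sd(covariate[ok]) == 0) {
    out[ok] <- y[ok] - mean(y[ok])
    return(structure(out, constant_covariate = TRUE))
  }
  fit <- lm.fit(cbind(1, covariate[ok]), y[ok])
  out[ok] <- fit$residuals
  out
}

#' Spatial correlation between two voxel maps
#'
#' Pearson correlation of two statistical maps over a shared set of voxels,
#' as used to compare weight maps before and after confound regression.
#'
#' @param map_a,map_b Numeric vectors of per-voxel values on the same voxel
#'   set (same length, same order).
#' @param mask Optional logical vector restricting the comparison.
#' @return Pearson r.
#' @export
spatial_correlation <- function(map_a, map_b, mask = NULL) {
  if (length(map_a) != length(map_b)) {
    stopf("maps are on different voxel sets (lengths %d and %d)",
          length(map_a), length(map_b))
  }
  if (!is.null(mask)) {
    if (length(mask) != length(map_a)) stopf("mask length does not match maps")
    map_a <- map_a[mask]; map_b <- map_b[mask]
  }
  if (length(map_a) < 3) stopf("need at least 3 voxels")
  cor(map_a, map_b)
}

#' Run the standard confound regression battery
#'
#' One simple regression per covariate column against the outcome, with
#' pairwise deletion, returned as a tidy table in the conventional
#' `(analysis, n, r, p)` format.
#'
#' @param data A data frame holding the outcome and covariates per subject.
#' @param outcome Name of the outcome column.
#' @param covariates Character vector of covariate column names; defaults to
#'   every other numeric column.
#' @return A tibble with one row per covariate: `analysis`, `n`, `r`, `p`.
#' @export
run_confound_regressions <- function(data, outcome, covariates = NULL) {
  data <- tibble::as_tibble(data)
  if (!outcome %in% names(data)) stopf("no column '%s'", outcome)
  if (is.null(covariates)) {
    covariates <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          outcome)
  }
  purrr::map_dfr(covariates, function(cv)
    simple_regression(data[[cv]], data[[outcome]], analysis = cv))
}
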