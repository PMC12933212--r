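#' Multivariate PLSR lesion-symptom map with full inference
#'
#' The complete multivariate mapping analysis for a continuous (or ordinal)
#' outcome such as the signed appetite-change score: PLSR fit of the outcome
#' on DTLVC lesion features, permutation test of the whole-map fit,
#' bootstrap voxel-wise z-statistics with a percentile confidence interval
#' on the in-sample R-squared, and family-wise error corrected voxel tests.
#'
#' @inheritParams fit_plsr
#' @param n_components Number of latent components; `NULL` (default) selects
#'   by cross-validation via [select_n_components()].
#' @param n_permutations,n_bootstrap Iteration counts (default 1000 each).
#' @param alpha_fwe Family-wise error level for voxel tests (default 0.05).
#' @param fwe_method `"holm"` (default): Holm-Bonferroni on normal-theory
#'   two-sided p-values of the bootstrap z. `"perm_maxz"`: permutation
#'   max-|z| distribution — each permuted-outcome refit is standardized by
#'   the observed bootstrap voxel SDs and the critical value is the
#'   `1 - alpha_fwe` quantile of the permutation maximum.
#' @param seed Master seed; permutation and bootstrap use independent
#'   substreams.
#' @return An object of class `plsr_map` with elements `weight_map`, `r2`,
#'   `r2_ci`, `perm_p`, `null_r2`, `z_map`, `fwe_map` (logical survivors),
#'   `zero_variance`, `voxels` (linear grid indices when `features` is a
#'   `dtlvc_features`), `grid`, `n_components`, `config`.
#' @seealso [tidy.plsr_map()], [glance.plsr_map()], [autoplot.plsr_map()]
#' @export
plsr_map <- function(features, y, n_components = NULL, n_permutations = 1000,
                     n_bootstrap = 1000, alpha_fwe = 0.05,
                     fwe_method = c("holm", "perm_maxz"), seed = 1,
                     standardize = FALSE) {
  fwe_method <- match.arg(fwe_method)
  X <- feature_matrix(features)
  y <- as.numeric(y)
  if (is.null(n_components)) {
    n_components <- select_n_components(features, y, seed = seed,
                                        standardize = standardize)
  }
  fit <- fit_plsr(X, y, n_components, standardize)
  boot <- bootstrap_voxel_stats(X, y, n_components, n_bootstrap, seed,
                                standardize)
  perm <- permute_model_fit(X, y, n_components, n_permutations, seed,
                            standardize)
  if (fwe_method == "holm") {
    fwe <- fwe_voxel_threshold(boot$z_map, alpha_fwe)
  } else {
    sdv <- ifelse(boot$zero_variance, Inf, boot$weight_sd)
    Xc <- scale(X, center = TRUE, scale = standardize)
    Xc[is.na(Xc)] <- 0
    null_max <- withr::with_seed(derive_seed(seed, 4L), {
      vapply(seq_len(n_permutations), function(b) {
        w <- simpls_core(Xc, sample(y), n_components)$coef
        max(abs(w / sdv))
      }, numeric(1))
    })
    k <- min(ceiling((1 - alpha_fwe) * (n_permutations + 1)), n_permutations)
    crit <- sort(null_max)[k]
    fwe <- structure(abs(boot$z_map) >= crit &
                       (1 + vapply(abs(boot$z_map), function(zz)
                         sum(null_max >= zz), numeric(1))) /
                       (n_permutations + 1) <= alpha_fwe,
                     crit_z = crit)
  }
  structure(
    list(weight_map = fit$weight_map, fitted = fit$fitted, r2 = fit$r2,
         r2_ci = boot$r2_ci, perm_p = perm$perm_p, null_r2 = perm$null_r2,
         z_map = boot$z_map, weight_sd = boot$weight_sd,
         zero_variance = boot$zero_variance,
         fwe_map = as.logical(fwe), p_holm = attr(fwe, "p_holm"),
         voxels = if (inherits(features, "dtlvc_features")) features$voxels,
         grid = if (inherits(features, "dtlvc_features")) features$grid,
         subject_ids = if (inherits(features, "dtlvc_features"))
           features$subject_ids,
         n_components = fit$n_components,
         config = list(n_permutations = n_permutations,
                       n_bootstrap = n_bootstrap, alpha_fwe = alpha_fwe,
                       fwe_method = fwe_method, seed = seed,
                       standardize = standardize)),
    class = "plsr_map"
  )
}

#' @export
print.plsr_map <- function(x, ...) {
  cat(sprintf(
    paste0("<plsr_map> %d voxels, %d component(s)\n",
           "  in-sample R2 = %.4f (95%% CI %.4f-%.4f), permutation p = %.4g\n",
           "  FWE-surviving voxels: %d\n"),
    length(x$weight_map), x$n_components, x$r2, x$r2_ci[1], x$r2_ci[2],
    x$perm_p, sum(x$fwe_map)))
  invisible(x)
}

#' Tidy a PLSR lesion-symptom map into a per-voxel tibble
#'
#' @param x A `plsr_map`.
#' @param ... Unused.
#' @return A tibble with one row per analysis-mask voxel: `voxel`, `i`, `j`,
#'   `k` (when grid information is available), `weight`, `z`, `p_fwe`
#'   (Holm-adjusted, when computed), `fwe_survivor`, `zero_variance`.
#' @method tidy plsr_map
#' @export
tidy.plsr_map <- function(x, ...) {
  base <- if (!is.null(x$grid)) voxel_coords(x$grid, x$voxels) else
    tibble::tibble(voxel = seq_along(x$weight_map))
  out <- dplyr::mutate(base, weight = x$weight_map, z = x$z_map,
                       fwe_survivor = x$fwe_map,
                       zero_variance = x$zero_variance)
  if (!is.null(x$p_holm)) out$p_fwe <- x$p_holm
  out
}

#' One-row summary of a PLSR lesion-symptom map
#'
#' @param x A `plsr_map`.
#' @param ... Unused.
#' @return A one-row tibble: `r2`, `r2_ci_low`, `r2_ci_high`, `perm_p`,
#'   `n_components`, `n_voxels`, `n_fwe_survivors`, `peak_abs_z`.
#' @method glance plsr_map
#' @export
glance.plsr_map <- function(x, ...) {
  tibble::tibble(
    r2 = x$r2, r2_ci_low = x$r2_ci[1], r2_ci_high = x$r2_ci[2],
    perm_p = x$perm_p, n_components = x$n_components,
    n_voxels = length(x$weight_map), n_fwe_survivors = sum(x$fwe_map),
    peak_abs_z = max(abs(x$z_map))
  )
}

plot_slices <- function(values, grid, voxels, slices, value_name) {
  df <- voxel_coords(grid, voxels)
  df$value <- values
  if (is.null(slices)) {
    ks <- sort(unique(df$k))
    slices <- ks[unique(round(seq(1, length(ks), length.out = min(9, length(ks)))))]
  }
  df <- dplyr::filter(df, .data$k %in% slices)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "grey95",
                                  high = "#b2182b", name = value_name) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Axial-slice montage of a PLSR voxel weight map
#'
#' @param object A `plsr_map` fitted from `dtlvc_features` (grid required).
#' @param what `"weight"` (default) or `"z"`.
#' @param slices Integer k-indices of axial slices; default an even spread.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot plsr_map
#' @export
autoplot.plsr_map <- function(object, what = c("weight", "z"), slices = NULL,
                              ...) {
  what <- match.arg(what)
  if (is.null(object$grid)) stopf("autoplot needs grid information")
  vals <- if (what == "weight") object$weight_map else object$z_map
  plot_slices(vals, object$grid, object$voxels, slices, what)
}

#' Write the maps of a PLSR result as NIfTI images
#'
#' Writes the voxel weight map, z-map and FWE survivor mask (values outside
#' the analysis mask are zero).
#'
#' @param x A `plsr_map` with grid information.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_plsr_maps <- function(x, dir, prefix = "appetite") {
  if (is.null(x$grid)) stopf("result carries no grid information")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  full <- function(v) {
    out <- numeric(n_voxels(x$grid))
    out[x$voxels] <- v
    out
  }
  paths <- c(
    weight = file.path(dir, paste0(prefix, "_weight.nii.gz")),
    z = file.path(dir, paste0(prefix, "_z.nii.gz")),
    fwe = file.path(dir, paste0(prefix, "_fwe_mask.nii.gz"))
  )
  write_map(full(x$weight_map), x$grid, paths["weight"])
  write_map(full(x$z_map), x$grid, paths["z"])
  write_map(full(as.numeric(x$fwe_map)), x$grid, paths["fwe"])
  invisible(paths)
}
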