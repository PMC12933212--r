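kth_largest <- function(x, v) {
  n <- length(x)
  sort(x, partial = n - v + 1)[n - v + 1]
}

group_vectors <- function(stack, groups) {
  groups <- as.integer(groups)
  if (length(groups) != nrow(stack$X)) {
    stopf("`groups` must have one -1/+1 label per subject")
  }
  if (!all(groups %in% c(-1L, 1L))) stopf("group labels must be -1 or +1")
  if (!any(groups == 1L) || !any(groups == -1L)) {
    stopf("both the -1 (loss) and +1 (gain) groups must be nonempty")
  }
  groups
}

#' Proportional lesion overlap within a subject group
#'
#' For each analysis-mask voxel, the fraction of group members whose lesion
#' covers that voxel.
#'
#' @param stack A `cohort_stack`.
#' @param members Logical or index vector selecting the group's subjects
#'   (rows of the stack).
#' @return Numeric vector over analysis-mask voxels, values in `[0, 1]`.
#' @export
proportional_overlap <- function(stack, members) {
  Xg <- stack$X[members, stack$analysis_mask, drop = FALSE]
  if (nrow(Xg) == 0) stopf("group is empty")
  colSums(Xg) / nrow(Xg)
}

#' Proportional difference map between outcome groups
#'
#' The mass-univariate statistic for binarized weight change: the per-voxel
#' lesion proportion in the +1 (weight gain) group minus the proportion in
#' the -1 (weight loss) group. Negative values mark damage preferentially
#' associated with weight loss.
#'
#' @param stack A `cohort_stack`.
#' @param groups Integer vector of -1/+1 labels, one per subject.
#' @return Numeric vector `D` over analysis-mask voxels, in `[-1, 1]`.
#' @export
proportional_difference <- function(stack, groups) {
  groups <- group_vectors(stack, groups)
  proportional_overlap(stack, groups == 1L) -
    proportional_overlap(stack, groups == -1L)
}

stat_transform <- function(D, alternative) {
  switch(alternative, two.sided = abs(D), greater = D, less = -D)
}

#' Permutation null for the proportional difference map
#'
#' Permutes the -1/+1 labels across subjects (preserving group sizes)
#' `n_permutations` times and records, per permutation, the `voxel_extent`-th
#' largest statistic over analysis-mask voxels, plus per-voxel exceedance
#' counts against the observed map. The statistic is `|D|` for the default
#' two-sided analysis; one-sided variants use signed `D`. Permuted maps are
#' computed in one matrix product per call, so the null costs a single
#' `V' x N` by `N x B` multiplication.
#'
#' @param stack A `cohort_stack`.
#' @param groups Integer -1/+1 labels.
#' @param n_permutations Number of label permutations (default 1000).
#' @param voxel_extent The extent threshold v; each permutation contributes
#'   its v-th largest statistic (default 1000).
#' @param alternative `"two.sided"` (default), `"greater"` (gain-associated)
#'   or `"less"` (loss-associated).
#' @param seed Integer seed.
#' @return A list with `vth_largest` (length `n_permutations`),
#'   `exceed_count` (per voxel: permutations whose statistic at that voxel
#'   is >= the observed statistic), `D_obs`, `n_permutations`,
#'   `voxel_extent`, `alternative`.
#' @export
permute_prop_diff <- function(stack, groups, n_permutations = 1000,
                              voxel_extent = 1000,
                              alternative = c("two.sided", "greater", "less"),
                              seed = 1) {
  alternative <- match.arg(alternative)
  groups <- group_vectors(stack, groups)
  Vp <- sum(stack$analysis_mask)
  if (voxel_extent < 1) stopf("voxel_extent must be >= 1")
  if (voxel_extent > Vp) {
    stopf(paste0("voxel_extent (%d) exceeds the %d analysis-mask voxels; ",
                 "no extent-passing result is possible on this grid"),
          voxel_extent, Vp)
  }
  n <- length(groups)
  np <- sum(groups == 1L); nm <- n - np
  Xm <- stack$X[, stack$analysis_mask, drop = FALSE]
  # D is lattice-valued: every value is an integer divided by np * nm. Both
  # the observed and the permuted maps are computed as exact integer
  # numerators over that common denominator, so exact ties stay exact ties
  # in floating point and >= comparisons are never broken by round-off.
  D_obs <- drop(crossprod(Xm, (groups == 1L) * nm - (groups == -1L) * np)) /
    (np * nm)
  s_obs <- stat_transform(D_obs, alternative)
  perm_labels <- withr::with_seed(derive_seed(seed, 1L), {
    vapply(seq_len(n_permutations), function(b) sample(groups),
           integer(n))
  })
  # all permutations in a single V' x N by N x B product, integer numerators
  Dnull <- crossprod(Xm, (perm_labels == 1L) * nm -
                       (perm_labels == -1L) * np) / (np * nm)
  Snull <- stat_transform(Dnull, alternative)
  vth_largest <- apply(Snull, 2, kth_largest, v = voxel_extent)
  exceed <- rowSums(Snull >= s_obs)
  list(vth_largest = vth_largest, exceed_count = exceed, D_obs = D_obs,
       n_permutations = n_permutations, voxel_extent = voxel_extent,
       alternative = alternative)
}

label_components <- function(voxels, dims) {
  # 26-connectivity components among `voxels` (linear indices); returns sizes
  if (!length(voxels)) return(integer(0))
  inset <- integer(prod(dims))
  inset[voxels] <- seq_along(voxels)
  coords <- arrayInd(voxels, dims)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  visited <- logical(length(voxels))
  sizes <- integer(0)
  for (s in seq_along(voxels)) {
    if (visited[s]) next
    queue <- s; visited[s] <- TRUE; size <- 0L
    while (length(queue)) {
      cur <- queue[length(queue)]; queue <- queue[-length(queue)]
      size <- size + 1L
      cc <- coords[cur, ]
      nb <- sweep(offs, 2, cc, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * dims[1] +
        (nb[, 3] - 1L) * dims[1] * dims[2]
      hit <- inset[lin]
      hit <- hit[hit > 0]
      hit <- hit[!visited[hit]]
      if (length(hit)) {
        visited[hit] <- TRUE
        queue <- c(queue, hit)
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

#' Continuous FWE threshold at a voxel-extent criterion
#'
#' The continuous family-wise error procedure determines a single critical
#' value for the whole map from the permutation distribution of the v-th
#' largest statistic (v = `voxel_extent`): under the null, fewer than v
#' voxels exceed the critical value in `1 - alpha_fwe` of permutations.
#' With `voxel_extent = 1` this reduces to the classical max-statistic FWE
#' test.
#'
#' The proportional-difference statistic is lattice-valued (ratios of small
#' integer counts), so exact ties between the observed map and permuted
#' values are common. The survivor set and the extent verdict therefore use
#' the exact add-one corrected p-value, which counts ties toward the null —
#' `p_fwe(v) = (1 + #\{b : vth-largest_b >= stat(v)\}) / (B + 1)` — and
#' remains valid under ties; without ties it coincides with thresholding at
#' the reported `crit_value` (the `ceiling((1-alpha)(B+1))`-th order
#' statistic of the null v-th largest values). Survivors are reported even
#' when the extent criterion fails, for exploratory uncorrected-p analysis.
#'
#' @param null Result of [permute_prop_diff()].
#' @param alpha_fwe Family-wise error level (default 0.05).
#' @param extent_rule `"global"` (default): the extent criterion counts all
#'   surviving voxels on the map. `"cluster"`: the largest 26-connected
#'   cluster of survivors must reach the extent (requires grid information
#'   via `dims` and `voxels`).
#' @param dims Grid dims, needed only for `extent_rule = "cluster"`.
#' @param voxels Global linear voxel indices of the analysis-mask columns,
#'   needed only for `extent_rule = "cluster"`.
#' @return A list with `crit_value`, `survivors` (logical over analysis-mask
#'   voxels), `n_survivors`, `extent_pass`, `fwe_p` (corrected p of the
#'   observed v-th largest statistic).
#' @export
continuous_fwe_threshold <- function(null, alpha_fwe = 0.05,
                                     extent_rule = c("global", "cluster"),
                                     dims = NULL, voxels = NULL) {
  extent_rule <- match.arg(extent_rule)
  B <- null$n_permutations
  s_obs <- stat_transform(null$D_obs, null$alternative)
  k <- min(ceiling((1 - alpha_fwe) * (B + 1)), B)
  crit_value <- sort(null$vth_largest)[k]
  null_sorted <- sort(null$vth_largest)
  # corrected p per voxel via binary search over the sorted null values
  p_corr <- (B - findInterval(s_obs, null_sorted, left.open = TRUE) + 1) /
    (B + 1)
  survivors <- p_corr <= alpha_fwe
  n_surv <- sum(survivors)
  extent_n <- if (extent_rule == "global") n_surv else {
    if (is.null(dims) || is.null(voxels)) {
      stopf("cluster extent rule needs grid `dims` and `voxels`")
    }
    sizes <- label_components(voxels[survivors], dims)
    if (length(sizes)) max(sizes) else 0L
  }
  obs_vth <- kth_largest(s_obs, null$voxel_extent)
  fwe_p <- (1 + sum(null$vth_largest >= obs_vth)) / (B + 1)
  list(crit_value = crit_value, survivors = survivors,
       n_survivors = n_surv, extent_pass = extent_n >= null$voxel_extent,
       fwe_p = fwe_p)
}

#' Uncorrected voxel-level permutation p-values
#'
#' For each voxel (conventionally reported for the FWE survivors), the
#' add-one permutation p-value of its statistic against that voxel's own
#' permutation distribution.
#'
#' @param null Result of [permute_prop_diff()].
#' @param survivors Optional logical vector; p-values are returned as `NA`
#'   elsewhere. Default: all voxels.
#' @return Numeric vector of p-values over analysis-mask voxels.
#' @export
uncorrected_voxel_p <- function(null, survivors = NULL) {
  p <- (1 + null$exceed_count) / (null$n_permutations + 1)
  if (!is.null(survivors)) p[!survivors] <- NA_real_
  p
}

#' Mass-univariate proportional-subtraction lesion map with inference
#'
#' The complete weight-change analysis: proportional overlap per group,
#' their difference map, permutation null, continuous-FWE critical value at
#' the voxel-extent threshold, and uncorrected voxel p-values for the
#' survivors.
#'
#' @inheritParams permute_prop_diff
#' @param alpha_fwe Family-wise error level (default 0.05).
#' @param alpha_uncorrected Level quoted for exploratory voxel-level tests
#'   (default 0.05).
#' @param extent_rule See [continuous_fwe_threshold()].
#' @return An object of class `prop_diff_map` with elements `d` (difference
#'   map over analysis-mask voxels), `p_plus`, `p_minus`, `crit_value`,
#'   `fwe_p`, `survivors`, `n_survivors`, `extent_pass`, `uncorrected_p`
#'   (NA outside survivors), `voxels`, `grid`, `group_sizes`, `config`.
#' @export
prop_diff_map <- function(stack, groups, n_permutations = 1000,
                          voxel_extent = 1000, alpha_fwe = 0.05,
                          alpha_uncorrected = 0.05,
                          alternative = c("two.sided", "greater", "less"),
                          extent_rule = c("global", "cluster"), seed = 1) {
  alternative <- match.arg(alternative)
  extent_rule <- match.arg(extent_rule)
  groups <- group_vectors(stack, groups)
  null <- permute_prop_diff(stack, groups, n_permutations, voxel_extent,
                            alternative, seed)
  fwe <- continuous_fwe_threshold(null, alpha_fwe, extent_rule,
                                  dims = stack$grid$dims,
                                  voxels = which(stack$analysis_mask))
  unc <- uncorrected_voxel_p(null, fwe$survivors)
  structure(
    list(d = null$D_obs,
         p_plus = proportional_overlap(stack, groups == 1L),
         p_minus = proportional_overlap(stack, groups == -1L),
         crit_value = fwe$crit_value, fwe_p = fwe$fwe_p,
         survivors = fwe$survivors, n_survivors = fwe$n_survivors,
         extent_pass = fwe$extent_pass, uncorrected_p = unc,
         voxels = which(stack$analysis_mask), grid = stack$grid,
         group_sizes = c(loss = sum(groups == -1L),
                         gain = sum(groups == 1L)),
         config = list(n_permutations = n_permutations,
                       voxel_extent = voxel_extent, alpha_fwe = alpha_fwe,
                       alpha_uncorrected = alpha_uncorrected,
                       alternative = alternative, extent_rule = extent_rule,
                       seed = seed)),
    class = "prop_diff_map"
  )
}

#' @export
print.prop_diff_map <- function(x, ...) {
  cat(sprintf(
    paste0("<prop_diff_map> %d voxels; groups: %d loss / %d gain\n",
           "  critical |D| = %.4f (FWE %.2g, extent %d): %d voxels survived, extent %s\n"),
    length(x$d), x$group_sizes["loss"], x$group_sizes["gain"],
    x$crit_value, x$config$alpha_fwe, x$config$voxel_extent,
    x$n_survivors, if (x$extent_pass) "PASSED" else "not passed"))
  invisible(x)
}

#' Tidy a proportional-difference map into a per-voxel tibble
#'
#' @param x A `prop_diff_map`.
#' @param ... Unused.
#' @return A tibble with one row per analysis-mask voxel: coordinates, `d`,
#'   `p_plus`, `p_minus`, `survivor`, `p_uncorrected`.
#' @method tidy prop_diff_map
#' @export
tidy.prop_diff_map <- function(x, ...) {
  dplyr::mutate(voxel_coords(x$grid, x$voxels),
                d = x$d, p_plus = x$p_plus, p_minus = x$p_minus,
                survivor = x$survivors, p_uncorrected = x$uncorrected_p)
}

#' One-row summary of a proportional-difference analysis
#'
#' @param x A `prop_diff_map`.
#' @param ... Unused.
#' @return A one-row tibble: `crit_value`, `fwe_p`, `n_survivors`,
#'   `extent_pass`, `min_d`, `max_d`, `n_loss`, `n_gain`.
#' @method glance prop_diff_map
#' @export
glance.prop_diff_map <- function(x, ...) {
  tibble::tibble(
    crit_value = x$crit_value, fwe_p = x$fwe_p,
    n_survivors = x$n_survivors, extent_pass = x$extent_pass,
    min_d = min(x$d), max_d = max(x$d),
    n_loss = unname(x$group_sizes["loss"]),
    n_gain = unname(x$group_sizes["gain"])
  )
}

#' Axial-slice montage of a proportional-difference map
#'
#' @param object A `prop_diff_map`.
#' @param slices Integer k-indices of axial slices; default an even spread.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prop_diff_map
#' @export
autoplot.prop_diff_map <- function(object, slices = NULL, ...) {
  plot_slices(object$d, object$grid, object$voxels, slices, "D")
}

#' Write the maps of a proportional-difference result as NIfTI images
#'
#' @param x A `prop_diff_map`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_prop_diff_maps <- function(x, dir, prefix = "weight") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  full <- function(v, fill = 0) {
    out <- rep(fill, n_voxels(x$grid))
    out[x$voxels] <- v
    out
  }
  paths <- c(
    d = file.path(dir, paste0(prefix, "_propdiff.nii.gz")),
    survivors = file.path(dir, paste0(prefix, "_survivors.nii.gz")),
    p = file.path(dir, paste0(prefix, "_uncorrected_p.nii.gz"))
  )
  write_map(full(x$d), x$grid, paths["d"])
  write_map(full(as.numeric(x$survivors)), x$grid, paths["survivors"])
  p <- x$uncorrected_p
  p[is.na(p)] <- 1
  write_map(full(p, fill = 1), x$grid, paths["p"])
  invisible(paths)
}
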