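#' Restrict the analysis mask to sufficiently lesioned voxels
#'
#' Voxels lesioned in fewer than `k` subjects carry too little information to
#' support stable voxel-level estimates; the conventional minimum for the
#' multivariate analysis is 10 subjects. The analysis mask is intersected
#' with `overlap >= k` (on top of any brain mask already present).
#'
#' @param stack A `cohort_stack`.
#' @param k Minimum lesion count per voxel (default 10).
#' @return The stack with its `analysis_mask` updated. A warning is issued if
#'   no voxel survives.
#' @export
min_overlap_filter <- function(stack, k = 10) {
  if (k < 1) stopf("`k` must be >= 1")
  stack$analysis_mask <- stack$analysis_mask & (stack$overlap >= k)
  if (!any(stack$analysis_mask)) {
    warn(sprintf(
      "no voxel is lesioned in at least %d subjects (max overlap %d); analysis mask is empty",
      k, max(stack$overlap)))
  }
  stack
}

#' DTLVC lesion-size normalization
#'
#' Direct total lesion volume control: each subject's binary lesion mask is
#' divided by the square root of that subject's total lesion volume, so every
#' full-grid row has unit sum of squares and large lesions cannot dominate
#' the predictor matrix simply by size. The divisor always uses the total
#' lesion volume over the whole grid; restriction to the analysis-mask
#' columns happens afterwards, so feature values do not depend on cohort
#' composition.
#'
#' @param stack A `cohort_stack`, typically after [min_overlap_filter()].
#' @return An object of class `dtlvc_features` with fields `X` (N x V' real
#'   matrix over analysis-mask voxels; entries are 0 or `1/sqrt(volume_i)`),
#'   `voxels` (linear indices of the analysis-mask voxels), `volumes`,
#'   `subject_ids`, `grid`.
#' @export
dtlvc_transform <- function(stack) {
  if (any(stack$volumes < 1)) stopf("every subject must have lesion volume >= 1")
  if (!any(stack$analysis_mask)) stopf("analysis mask is empty")
  voxels <- which(stack$analysis_mask)
  X <- stack$X[, voxels, drop = FALSE] / sqrt(stack$volumes)
  structure(
    list(X = X, voxels = voxels, volumes = stack$volumes,
         subject_ids = stack$subject_ids, grid = stack$grid),
    class = "dtlvc_features"
  )
}

#' @export
print.dtlvc_features <- function(x, ...) {
  cat(sprintf("<dtlvc_features> %d subjects x %d voxels (of %d on grid)\n",
              nrow(x$X), ncol(x$X), n_voxels(x$grid)))
  invisible(x)
}
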