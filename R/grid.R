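#' Define a common voxel grid
#'
#' All lesion masks and statistical maps in an analysis live on one shared
#' voxel grid: an array shape, a physical voxel size, a voxel-to-world affine,
#' and optionally a binary brain mask restricting which voxels are considered
#' in-brain. Real cohorts are typically registered to MNI152 space upstream;
#' any grid is accepted here and no resampling is ever performed — a grid
#' mismatch between images is an error, not a warning.
#'
#' @param dims Integer vector of length 3: voxels per axis.
#' @param voxel_size Numeric length 3, voxel edge lengths in mm.
#' @param affine 4x4 voxel-to-world transform. Defaults to a diagonal scaling
#'   by `voxel_size` (0-based voxel indices to mm).
#' @param brain_mask Optional logical/0-1 3-D array of shape `dims` marking
#'   in-brain voxels.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(24, 24, 24))
#' n_voxels(g)
#' @export
voxel_grid <- function(dims, voxel_size = c(1, 1, 1), affine = NULL,
                       brain_mask = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(dims < 1)) {
    stopf("`dims` must be three integers >= 1")
  }
  if (length(voxel_size) != 3 || any(voxel_size <= 0)) {
    stopf("`voxel_size` must be three positive lengths (mm)")
  }
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- matrix(as.numeric(affine), 4, 4)
  if (abs(det(affine)) < .Machine$double.eps) {
    stopf("grid affine must be invertible")
  }
  if (!is.null(brain_mask)) {
    brain_mask <- array(as.logical(brain_mask), dim = dim(brain_mask))
    if (!identical(dim(brain_mask), dims)) {
      stopf("`brain_mask` shape (%s) does not match grid dims (%s)",
            paste(dim(brain_mask), collapse = "x"),
            paste(dims, collapse = "x"))
    }
  }
  structure(
    list(dims = dims, voxel_size = as.numeric(voxel_size),
         affine = affine, brain_mask = brain_mask),
    class = "voxel_grid"
  )
}

#' Number of voxels in a grid
#' @param grid A [voxel_grid()].
#' @return Integer voxel count, `prod(dims)`.
#' @export
n_voxels <- function(grid) prod(grid$dims)

#' Voxel index coordinates of a grid
#'
#' Voxels are stored in a fixed column-major linear order (first axis fastest),
#' the native order of R arrays, so that any per-voxel vector can be
#' reassembled into a 3-D array with `array(x, grid$dims)` and weight maps are
#' reproducible across runs and machines.
#'
#' @param grid A [voxel_grid()].
#' @param voxels Optional integer vector of linear voxel indices (1-based);
#'   default all voxels.
#' @return A tibble with integer columns `voxel`, `i`, `j`, `k` (1-based).
#' @export
voxel_coords <- function(grid, voxels = NULL) {
  if (is.null(voxels)) voxels <- seq_len(n_voxels(grid))
  idx <- arrayInd(voxels, grid$dims)
  tibble::tibble(voxel = as.integer(voxels),
                 i = idx[, 1], j = idx[, 2], k = idx[, 3])
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$dims, b$dims) &&
    max(abs(a$affine - b$affine)) <= tol &&
    max(abs(a$voxel_size - b$voxel_size)) <= tol
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels, %s mm%s\n",
              paste(x$dims, collapse = " x "),
              paste(signif(x$voxel_size, 3), collapse = " x "),
              if (is.null(x$brain_mask)) "" else
                sprintf(", brain mask (%d voxels)", sum(x$brain_mask))))
  invisible(x)
}
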