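#' Construct a lesion mask from a binary array
#'
#' @param data 3-D array of 0/1 (or logical) lesion status.
#' @param grid The [voxel_grid()] the mask lives on.
#' @param subject_id Subject identifier string.
#' @return An object of class `lesion_mask` with fields `subject_id`, `data`
#'   (integer 0/1 array), `volume` (lesioned voxel count) and `grid`.
#' @export
lesion_mask <- function(data, grid, subject_id) {
  if (!identical(as.integer(dim(data)), grid$dims)) {
    stopf("mask dims (%s) do not match grid dims (%s) for subject '%s'",
          paste(dim(data), collapse = "x"),
          paste(grid$dims, collapse = "x"), subject_id)
  }
  data <- array(as.integer(as.logical(data)), dim = grid$dims)
  vol <- sum(data)
  if (vol < 1) stopf("subject '%s' has an empty lesion mask", subject_id)
  structure(list(subject_id = as.character(subject_id), data = data,
                 volume = as.integer(vol), grid = grid),
            class = "lesion_mask")
}

#' Read a binary lesion mask from a NIfTI file
#'
#' The image is binarized at `binarize_threshold` to guard against small
#' interpolation artefacts in nominally binary masks. The image dimensions
#' must match the grid exactly; no resampling is attempted.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param grid Target [voxel_grid()].
#' @param binarize_threshold Values strictly greater than this are lesioned.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extensions.
#' @return A `lesion_mask`.
#' @export
read_lesion_mask <- function(path, grid, binarize_threshold = 0.5,
                             subject_id = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) > 3) arr <- array(arr, dim = dim(arr)[1:3])
  if (!identical(as.integer(dim(arr)), grid$dims)) {
    stopf("image dims (%s) in %s do not match grid dims (%s)",
          paste(dim(arr), collapse = "x"), path,
          paste(grid$dims, collapse = "x"))
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  lesion_mask(arr > binarize_threshold, grid, subject_id)
}

#' Stack lesion masks into a cohort matrix
#'
#' Assembles the subjects-by-voxels binary predictor matrix used by every
#' downstream analysis, together with the per-voxel lesion overlap count and
#' an analysis mask (initially all in-grid voxels, or the brain mask when the
#' grid carries one). Rows follow the input order; columns follow the fixed
#' voxel order described in [voxel_coords()].
#'
#' @param masks A list of `lesion_mask` objects sharing one grid.
#' @return An object of class `cohort_stack` with fields `grid`,
#'   `subject_ids`, `X` (N x V integer matrix), `volumes`, `overlap`
#'   (per-voxel lesion counts) and `analysis_mask` (logical per voxel).
#' @export
stack_cohort <- function(masks) {
  if (length(masks) < 1) stopf("need at least one lesion mask")
  grid <- masks[[1]]$grid
  ok <- vapply(masks, function(m) same_grid(m$grid, grid), logical(1))
  if (!all(ok)) stopf("masks are on mixed grids (first mismatch: subject '%s')",
                      masks[[which(!ok)[1]]]$subject_id)
  ids <- vapply(masks, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) {
    stopf("duplicate subject_id: %s", ids[duplicated(ids)][1])
  }
  V <- n_voxels(grid)
  X <- matrix(0L, nrow = length(masks), ncol = V)
  for (i in seq_along(masks)) X[i, ] <- as.integer(masks[[i]]$data)
  analysis_mask <- if (is.null(grid$brain_mask)) rep(TRUE, V) else
    as.logical(grid$brain_mask)
  structure(
    list(grid = grid, subject_ids = ids, X = X,
         volumes = vapply(masks, `[[`, integer(1), "volume"),
         overlap = colSums(X), analysis_mask = analysis_mask),
    class = "cohort_stack"
  )
}

#' Read a cohort of lesion masks from a CSV manifest
#'
#' @param manifest Path to a CSV with columns `subject_id` and `mask_path`
#'   (paths relative to the manifest's directory or absolute).
#' @param grid Target [voxel_grid()].
#' @param binarize_threshold Passed to [read_lesion_mask()].
#' @return A `cohort_stack`.
#' @export
read_cohort <- function(manifest, grid, binarize_threshold = 0.5) {
  tab <- read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "mask_path") %in% names(tab))) {
    stopf("manifest must have columns subject_id, mask_path")
  }
  base <- dirname(manifest)
  masks <- lapply(seq_len(nrow(tab)), function(i) {
    p <- tab$mask_path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    read_lesion_mask(p, grid, binarize_threshold,
                     subject_id = tab$subject_id[i])
  })
  stack_cohort(masks)
}

#' Per-voxel lesion overlap map
#'
#' Counts, for each voxel, how many subjects in the cohort have a lesion
#' there — the map conventionally displayed to show cohort lesion coverage.
#'
#' @param stack A `cohort_stack`.
#' @return Numeric vector of length `n_voxels(grid)` of lesion counts, with
#'   attribute `max_overlap`.
#' @export
overlap_map <- function(stack) {
  structure(as.numeric(stack$overlap), max_overlap = max(stack$overlap))
}

#' Write a per-voxel map as a NIfTI image
#'
#' @param map Numeric vector of length `n_voxels(grid)`, or a 3-D array of
#'   the grid's shape.
#' @param grid The [voxel_grid()] defining shape and affine.
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, grid, path) {
  if (is.array(map) && length(dim(map)) == 3) map <- as.vector(map)
  if (length(map) != n_voxels(grid)) {
    stopf("map length (%d) does not match grid voxel count (%d)",
          length(map), n_voxels(grid))
  }
  img <- RNifti::asNifti(array(as.numeric(map), dim = grid$dims))
  RNifti::pixdim(img) <- grid$voxel_size
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a per-voxel map written by [write_map()]
#'
#' @param path NIfTI file path.
#' @param grid Expected [voxel_grid()]; dims are checked.
#' @return Numeric vector of per-voxel values in the fixed voxel order.
#' @export
read_map <- function(path, grid) {
  arr <- as.array(RNifti::readNifti(path))
  if (!identical(as.integer(dim(arr)[1:3]), grid$dims)) {
    stopf("map dims in %s do not match grid", path)
  }
  as.numeric(arr)
}

#' @export
print.cohort_stack <- function(x, ...) {
  cat(sprintf(
    "<cohort_stack> %d subjects on a %s grid; max overlap %d; %d voxels in analysis mask\n",
    length(x$subject_ids), paste(x$grid$dims, collapse = "x"),
    max(x$overlap), sum(x$analysis_mask)))
  invisible(x)
}
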