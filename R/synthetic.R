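#' Configuration for a synthetic lesion cohort
#'
#' Defines the study conditions for a simulated cohort: a voxel grid, a
#' number of subjects, a lesion-volume range, an optional spatial prior for
#' lesion seed placement, a ground-truth region whose damage drives the
#' outcome, an effect size, a noise level, and the outcome kind. Defaults
#' emulate the structure of a chronic focal-lesion registry cohort at a size
#' that keeps full analyses fast on one CPU: a 24^3 grid, 100 subjects,
#' lesion volumes 50-400 voxels with seeds mildly concentrated toward the
#' grid centre, and a spherical truth region. With the default appetite
#' settings (effect 2 per unit DTLVC load, unit latent noise) roughly 30% of
#' subjects report decreased appetite, 25% increased and 45% no change;
#' the default weight settings (effect 1, 5% noise) split the cohort into
#' near-equal loss/gain groups with single-digit per-cent changes.
#'
#' @param grid_dims Grid shape (default `c(24, 24, 24)`).
#' @param n_subjects Number of subjects (default 100).
#' @param volume_range Lesion volume range in voxels (default `c(50, 400)`).
#' @param spatial_prior Optional non-negative 3-D density array (grid shape)
#'   from which lesion seed voxels are drawn; default a centre-weighted
#'   Gaussian falloff that mimics the clustering of vascular lesions around
#'   well-covered territory.
#' @param truth_region Integer linear voxel indices of the ground-truth
#'   region; default a central ball of radius `min(dims)/6` voxels.
#' @param effect_size Latent outcome shift per unit DTLVC load on the truth
#'   region (appetite: latent scale units; weight: per-cent change). Default
#'   2 for appetite, 1 for weight.
#' @param noise_sd Gaussian noise SD on the latent outcome (default 1 for
#'   appetite, 5 for weight, in the respective units).
#' @param outcome `"appetite"` or `"weight"`.
#' @param seed Master seed; every subject draws from an independent
#'   substream, so enlarging the cohort never reshuffles earlier subjects.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(grid_dims = c(24, 24, 24), n_subjects = 100,
                       volume_range = c(50, 400), spatial_prior = NULL,
                       truth_region = NULL, effect_size = NULL,
                       noise_sd = NULL, outcome = c("appetite", "weight"),
                       seed = 1) {
  outcome <- match.arg(outcome)
  grid <- voxel_grid(grid_dims)
  if (max(volume_range) > n_voxels(grid)) {
    stopf("requested lesion volume exceeds grid capacity")
  }
  if (is.null(truth_region)) {
    truth_region <- truth_ball(grid, radius = min(grid_dims) / 6)
  }
  if (!all(truth_region >= 1 & truth_region <= n_voxels(grid))) {
    stopf("truth_region indices fall outside the grid")
  }
  if (is.null(effect_size)) effect_size <- if (outcome == "appetite") 2 else 1
  if (is.null(noise_sd)) noise_sd <- if (outcome == "appetite") 1 else 5
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(
    list(grid = grid, n_subjects = as.integer(n_subjects),
         volume_range = as.integer(volume_range),
         spatial_prior = spatial_prior,
         truth_region = as.integer(truth_region),
         effect_size = effect_size, noise_sd = noise_sd,
         outcome = outcome, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Spherical truth region on a grid
#'
#' @param grid A [voxel_grid()].
#' @param centre Voxel coordinates of the ball centre (default grid centre).
#' @param radius Radius in voxels.
#' @return Integer linear voxel indices.
#' @export
truth_ball <- function(grid, centre = NULL, radius = 4) {
  if (is.null(centre)) centre <- (grid$dims + 1) / 2
  cc <- voxel_coords(grid)
  d2 <- (cc$i - centre[1])^2 + (cc$j - centre[2])^2 + (cc$k - centre[3])^2
  which(d2 <= radius^2)
}

# Single connected lesion grown by random neighbour accretion
# (6-connectivity) from a seed voxel to the requested volume. Candidate
# voxels are held in a flat vector with a membership flag so each growth
# step is O(1).
grow_lesion <- function(dims, volume, seed_voxel) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  nvox <- nx * ny * nz
  if (volume > nvox) stopf("requested lesion volume exceeds the grid")
  occ <- logical(nvox)
  cand_flag <- logical(nvox)
  nb6 <- function(idx) {
    i0 <- (idx - 1L) %% nx
    j0 <- ((idx - 1L) %/% nx) %% ny
    k0 <- (idx - 1L) %/% (nx * ny)
    out <- integer(0)
    if (i0 > 0L) out <- c(out, idx - 1L)
    if (i0 < nx - 1L) out <- c(out, idx + 1L)
    if (j0 > 0L) out <- c(out, idx - nx)
    if (j0 < ny - 1L) out <- c(out, idx + nx)
    if (k0 > 0L) out <- c(out, idx - nx * ny)
    if (k0 < nz - 1L) out <- c(out, idx + nx * ny)
    out
  }
  occ[seed_voxel] <- TRUE
  sel <- integer(volume)
  sel[1] <- seed_voxel
  count <- 1L
  cand <- nb6(seed_voxel)
  cand_flag[cand] <- TRUE
  while (count < volume && length(cand)) {
    pick <- sample.int(length(cand), 1L)
    v <- cand[pick]
    cand[pick] <- cand[length(cand)]
    cand <- cand[-length(cand)]
    cand_flag[v] <- FALSE
    occ[v] <- TRUE
    count <- count + 1L
    sel[count] <- v
    nb <- nb6(v)
    nb <- nb[!occ[nb] & !cand_flag[nb]]
    if (length(nb)) {
      cand <- c(cand, nb)
      cand_flag[nb] <- TRUE
    }
  }
  sel[seq_len(count)]
}

default_prior_seed <- function(dims) {
  # centre-biased Gaussian seed placement, truncated to the grid
  pmin(pmax(round(rnorm(3, dims / 2, dims / 5)), 1), dims)
}

#' Generate a cohort of synthetic lesion masks
#'
#' Each lesion is one connected component grown by random neighbour
#' accretion (6-connectivity) from a seed voxel to a volume drawn uniformly
#' from the configured range. Seeds are drawn from the spatial prior (or the
#' default centre-weighted rule), producing the spatial clustering of
#' overlap seen in registry cohorts. Each subject uses an independent seed
#' substream.
#'
#' @param config A [sim_config()].
#' @return A list of `lesion_mask` objects with ids `"S001"`, `"S002"`, ...
#' @export
generate_lesions <- function(config) {
  dims <- config$grid$dims
  prior <- config$spatial_prior
  if (!is.null(prior)) {
    prior_p <- as.numeric(prior)
    if (length(prior_p) != n_voxels(config$grid) || any(prior_p < 0)) {
      stopf("spatial_prior must be a non-negative array of the grid shape")
    }
  }
  lapply(seq_len(config$n_subjects), function(s) {
    withr::with_seed(derive_seed(config$seed, 100L + s), {
      vol <- sample(config$volume_range[1]:config$volume_range[2], 1L)
      seed_voxel <- if (is.null(prior)) {
        ijk <- default_prior_seed(dims)
        ijk[1] + (ijk[2] - 1L) * dims[1] + (ijk[3] - 1L) * dims[1] * dims[2]
      } else {
        sample.int(length(prior_p), 1L, prob = prior_p)
      }
      idx <- grow_lesion(dims, vol, seed_voxel)
      arr <- array(0L, dims)
      arr[idx] <- 1L
      lesion_mask(arr, config$grid, sprintf("S%03d", s))
    })
  })
}

truth_load <- function(masks, truth_region) {
  vapply(masks, function(m)
    sum(m$data[truth_region]) / sqrt(m$volume), numeric(1))
}

#' Generate BDI-II item-18 appetite records for synthetic lesions
#'
#' The latent appetite change is `-effect_size * load + noise`, where `load`
#' is the subject's DTLVC-scale lesion load on the truth region (truth
#' voxels lesioned divided by the square root of lesion volume) — damage to
#' the truth region pushes appetite down. The latent value is discretized at
#' the symmetric cut points -2.5, -1.5, -0.5, +0.5, +1.5, +2.5 into signed
#' scores -3..+3 and emitted as raw item-18 codes with chronic-phase day
#' offsets (>= 90 days) and a BDI total.
#'
#' @param masks List of `lesion_mask` objects.
#' @param config A [sim_config()] (its `truth_region`, `effect_size`,
#'   `noise_sd`, `seed` are used).
#' @return A tibble with columns `subject_id`, `day_offset`, `item18_code`,
#'   `bdi_total`.
#' @export
generate_appetite_outcomes <- function(masks, config) {
  if (!length(config$truth_region)) stopf("truth_region is empty")
  load <- truth_load(masks, config$truth_region)
  purrr::map_dfr(seq_along(masks), function(s) {
    m <- masks[[s]]
    ld <- load[s]
    withr::with_seed(derive_seed(config$seed, 200000L + s), {
      u <- -config$effect_size * ld +
        if (config$noise_sd > 0) rnorm(1, 0, config$noise_sd) else 0
      score <- max(min(as.integer(round(u)), 3L), -3L)
      bdi_rest <- sample(0:30, 1)
      tibble::tibble(
        subject_id = m$subject_id,
        day_offset = sample(90:1000, 1),
        item18_code = appetite_item_code(score),
        bdi_total = bdi_rest + abs(score)
      )
    })
  })
}

#' Generate dated weight records for synthetic lesions
#'
#' Per subject: a baseline weight W1 drawn in 50-120 kg at a day in
#' `[0, 90]`, and a follow-up W2 at a day in `[120, 1000]` (so the pair
#' always satisfies the selection windows, including the 30-day gap). The
#' per-cent change is `-effect_size * load + noise` (clamped above -80% so
#' weights stay positive), with `load` the DTLVC-scale lesion load on the
#' truth region: truth-region damage drives weight loss.
#'
#' @inheritParams generate_appetite_outcomes
#' @return A long tibble with columns `subject_id`, `day_offset`,
#'   `weight_kg` (two rows per subject).
#' @export
generate_weight_outcomes <- function(masks, config) {
  if (!length(config$truth_region)) stopf("truth_region is empty")
  load <- truth_load(masks, config$truth_region)
  purrr::map_dfr(seq_along(masks), function(s) {
    m <- masks[[s]]
    ld <- load[s]
    withr::with_seed(derive_seed(config$seed, 300000L + s), {
      pct <- -config$effect_size * ld +
        if (config$noise_sd > 0) rnorm(1, 0, config$noise_sd) else 0
      pct <- max(pct, -80)
      w1 <- runif(1, 50, 120)
      tibble::tibble(
        subject_id = m$subject_id,
        day_offset = c(sample(0:90, 1), sample(120:1000, 1)),
        weight_kg = c(w1, w1 * (1 + pct / 100))
      )
    })
  })
}

#' Simulate a complete lesion cohort with outcomes
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_cohort` with elements `masks`, `stack`
#'   (the assembled `cohort_stack`), `outcomes` (raw behavioural records in
#'   the same schema the real-data readers expect), `truth` (truth region,
#'   effect size, noise SD, seed), `config`.
#' @export
simulate_cohort <- function(config) {
  masks <- generate_lesions(config)
  outcomes <- if (config$outcome == "appetite") {
    generate_appetite_outcomes(masks, config)
  } else {
    generate_weight_outcomes(masks, config)
  }
  structure(
    list(masks = masks, stack = stack_cohort(masks), outcomes = outcomes,
         truth = list(truth_region = config$truth_region,
                      effect_size = config$effect_size,
                      noise_sd = config$noise_sd, seed = config$seed),
         config = config),
    class = "synthetic_cohort"
  )
}

#' Write a synthetic cohort to disk in the real-data interchange formats
#'
#' NIfTI mask per subject, a CSV mask manifest, a CSV behavioural table, and
#' a JSON manifest recording the generating configuration and seed.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mask_dir <- file.path(dir, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  paths <- vapply(cohort$masks, function(m) {
    p <- file.path(mask_dir, paste0(m$subject_id, ".nii.gz"))
    write_map(m$data, m$grid, p)
    p
  }, character(1))
  write.csv(
    data.frame(subject_id = vapply(cohort$masks, `[[`, character(1),
                                   "subject_id"),
               mask_path = file.path("masks", basename(paths))),
    file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(cohort$outcomes, file.path(dir, "behaviour.csv"),
            row.names = FALSE)
  cfg <- cohort$config
  jsonlite::write_json(
    list(grid_dims = cfg$grid$dims, n_subjects = cfg$n_subjects,
         volume_range = cfg$volume_range, outcome = cfg$outcome,
         effect_size = cfg$effect_size, noise_sd = cfg$noise_sd,
         n_truth_voxels = length(cfg$truth_region), seed = cfg$seed),
    file.path(dir, "sim_config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
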