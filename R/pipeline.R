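resolve_masks <- function(masks, grid = NULL, binarize_threshold = 0.5) {
  if (inherits(masks, "cohort_stack")) return(masks)
  if (is.character(masks)) {
    if (is.null(grid)) stopf("reading a manifest requires a `grid`")
    return(read_cohort(masks, grid, binarize_threshold))
  }
  stack_cohort(masks)
}

resolve_table <- function(behaviour) {
  if (is.character(behaviour)) {
    tibble::as_tibble(read.csv(behaviour, stringsAsFactors = FALSE))
  } else {
    tibble::as_tibble(behaviour)
  }
}

pkg_version_string <- function() {
  as.character(utils::packageVersion("lesionmapr"))
}

report_skeleton <- function(mode, config, seed) {
  list(mode = mode, version = pkg_version_string(), seed = seed,
       config = config)
}

subset_stack <- function(stack, ids) {
  keep <- match(ids, stack$subject_ids)
  if (anyNA(keep)) stopf("behavioural ids missing from the mask cohort: %s",
                         paste(head(ids[is.na(keep)], 3), collapse = ", "))
  stack$X <- stack$X[keep, , drop = FALSE]
  stack$subject_ids <- stack$subject_ids[keep]
  stack$volumes <- stack$volumes[keep]
  stack$overlap <- colSums(stack$X)
  stack
}

#' Run the appetite-change lesion-symptom analysis end to end
#'
#' Constructs chronic-phase signed appetite scores from raw item-18 records,
#' aligns them with the lesion cohort, applies the minimum-overlap filter
#' and DTLVC normalization, and fits the full PLSR map with permutation and
#' bootstrap inference. Optionally repeats the fit on the outcome
#' residualized against depression severity (BDI total minus the appetite
#' item) and reports the spatial correlation of the two weight maps.
#'
#' @param masks A list of `lesion_mask`, a `cohort_stack`, or a manifest CSV
#'   path (then `grid` is required).
#' @param behaviour A data frame or CSV path with columns `subject_id`,
#'   `day_offset`, `item18_code`, `bdi_total`.
#' @param grid Required when `masks` is a manifest path.
#' @param k Minimum per-voxel lesion count (default 10).
#' @param chronic_min_days Chronic-phase threshold in days (default 90).
#' @param residualize_bdi Also run the depression-residualized analysis
#'   (default FALSE).
#' @param seed Master seed for permutation and bootstrap streams.
#' @param output_dir If given, NIfTI maps and a JSON report are written
#'   there.
#' @inheritParams plsr_map
#' @return A list of class `lsm_report`: `mode`, `version`, `seed`,
#'   `config`, `counts` (subject accounting from raw records to analysed),
#'   `result` (the `plsr_map`), `summary` (its [glance()]), and when
#'   requested `residualized` (second `plsr_map`) plus
#'   `spatial_correlation`.
#' @export
run_appetite_analysis <- function(masks, behaviour, grid = NULL, k = 10,
                                  n_components = NULL, n_permutations = 1000,
                                  n_bootstrap = 1000, alpha_fwe = 0.05,
                                  chronic_min_days = 90,
                                  residualize_bdi = FALSE, seed = 1,
                                  standardize = FALSE, output_dir = NULL) {
  stack <- resolve_masks(masks, grid)
  records <- resolve_table(behaviour)
  scores <- appetite_scores(records, chronic_min_days)
  n_chronic <- nrow(scores)
  excluded_ids <- attr(scores, "excluded_subjects")
  scores <- scores[scores$subject_id %in% stack$subject_ids, ]
  if (nrow(scores) < 3) {
    stopf("only %d subjects have a chronic appetite score and a lesion mask; need >= 3",
          nrow(scores))
  }
  stack <- subset_stack(stack, scores$subject_id)
  stack <- min_overlap_filter(stack, k)
  if (!any(stack$analysis_mask)) {
    stopf("analysis mask is empty at k = %d (max overlap %d); lower `k`",
          k, max(stack$overlap))
  }
  feats <- dtlvc_transform(stack)
  res <- plsr_map(feats, scores$score, n_components, n_permutations,
                  n_bootstrap, alpha_fwe, seed = seed,
                  standardize = standardize)
  report <- report_skeleton(
    "appetite-map",
    list(k = k, n_permutations = n_permutations, n_bootstrap = n_bootstrap,
         alpha_fwe = alpha_fwe, chronic_min_days = chronic_min_days,
         n_components = res$n_components, standardize = standardize),
    seed)
  report$counts <- list(
    n_raw_subjects = length(unique(records$subject_id)),
    n_with_chronic_score = n_chronic,
    n_analysed = nrow(scores),
    excluded_no_chronic_assessment = excluded_ids,
    n_voxels_analysed = sum(stack$analysis_mask))
  report$result <- res
  report$summary <- glance(res)
  if (residualize_bdi) {
    y_res <- residualize(scores$score, scores$bdi_total_minus_appetite)
    res2 <- plsr_map(feats, y_res, res$n_components, n_permutations,
                     n_bootstrap, alpha_fwe, seed = seed,
                     standardize = standardize)
    report$residualized <- res2
    report$spatial_correlation <-
      spatial_correlation(res$weight_map, res2$weight_map)
  }
  report <- structure(report, class = "lsm_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' Run the weight-change lesion-mapping analysis end to end
#'
#' Constructs per-cent weight changes under the W1/W2 selection windows,
#' binarizes them into loss (-1) and gain (+1) groups, applies the
#' minimum-overlap filter (default 2 for this analysis: weight cohorts are
#' small and their maximum overlap commonly falls below the 10 used in the
#' appetite analysis), and runs the proportional-subtraction map with
#' continuous-FWE inference. Optionally repeats the analysis on the
#' clinically significant (> `clinical_threshold_pct`) subset.
#'
#' @inheritParams run_appetite_analysis
#' @inheritParams prop_diff_map
#' @param behaviour A data frame or CSV path with columns `subject_id`,
#'   `day_offset`, `weight_kg` (long format).
#' @param k Minimum per-voxel lesion count (default 2).
#' @param w1_max_day,w2_min_day,w2_max_day,min_gap_days Selection windows,
#'   see [weight_changes()].
#' @param zero_change Handling of exactly-zero change, see
#'   [binarize_weight_change()].
#' @param clinical_subset Also analyse the clinically significant subset
#'   (default FALSE).
#' @param clinical_threshold_pct Per-cent threshold for that subset
#'   (default 5).
#' @return A list of class `lsm_report` with `result` (a `prop_diff_map`),
#'   `summary`, `changes` (the constructed weight-change table), counts, and
#'   when requested `clinical` (subset `prop_diff_map`).
#' @export
run_weight_analysis <- function(masks, behaviour, grid = NULL, k = 2,
                                n_permutations = 1000, voxel_extent = 1000,
                                alpha_fwe = 0.05, alpha_uncorrected = 0.05,
                                w1_max_day = 90, w2_min_day = 90,
                                w2_max_day = 1000, min_gap_days = 30,
                                zero_change = "exclude",
                                clinical_subset = FALSE,
                                clinical_threshold_pct = 5,
                                alternative = "two.sided",
                                extent_rule = "global", seed = 1,
                                output_dir = NULL) {
  stack <- resolve_masks(masks, grid)
  records <- resolve_table(behaviour)
  changes <- weight_changes(records, w1_max_day, w2_min_day, w2_max_day,
                            min_gap_days, zero_change)
  excluded_ids <- attr(changes, "excluded_subjects")
  changes <- changes[changes$subject_id %in% stack$subject_ids &
                       !is.na(changes$group_code), ]
  if (nrow(changes) < 3) stopf("only %d subjects usable; need >= 3",
                               nrow(changes))
  run_one <- function(ch, vext) {
    st <- subset_stack(stack, ch$subject_id)
    st <- min_overlap_filter(st, k)
    if (!any(st$analysis_mask)) {
      stopf("analysis mask is empty at k = %d (max overlap %d); lower `k`",
            k, max(st$overlap))
    }
    if (vext > sum(st$analysis_mask)) {
      warn(sprintf(
        "voxel_extent (%d) exceeds the %d analysis-mask voxels; capping at the mask size (the extent criterion cannot pass)",
        vext, sum(st$analysis_mask)))
      vext <- sum(st$analysis_mask)
    }
    prop_diff_map(st, ch$group_code, n_permutations, vext, alpha_fwe,
                  alpha_uncorrected, alternative, extent_rule, seed)
  }
  res <- run_one(changes, voxel_extent)
  report <- report_skeleton(
    "weight-map",
    list(k = k, n_permutations = n_permutations,
         voxel_extent = voxel_extent, alpha_fwe = alpha_fwe,
         alpha_uncorrected = alpha_uncorrected,
         windows = list(w1_max_day = w1_max_day, w2_min_day = w2_min_day,
                        w2_max_day = w2_max_day,
                        min_gap_days = min_gap_days),
         zero_change = zero_change, alternative = alternative,
         extent_rule = extent_rule),
    seed)
  report$counts <- list(
    n_raw_subjects = length(unique(records$subject_id)),
    n_analysed = nrow(changes),
    n_loss = sum(changes$group_code == -1),
    n_gain = sum(changes$group_code == 1),
    excluded_no_valid_pair = excluded_ids,
    n_voxels_analysed = length(res$voxels))
  report$changes <- changes
  report$result <- res
  report$summary <- glance(res)
  if (clinical_subset) {
    sub <- clinically_significant(changes, clinical_threshold_pct)
    if (nrow(sub) >= 3 && length(unique(sub$group_code)) == 2) {
      report$clinical <- run_one(sub, voxel_extent)
      report$counts$n_clinical <- nrow(sub)
    } else {
      warn("clinically significant subset too small or one-sided; skipped")
    }
  }
  report <- structure(report, class = "lsm_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

report_json_payload <- function(report) {
  out <- list(mode = report$mode, version = report$version,
              seed = report$seed, config = report$config,
              counts = report$counts,
              summary = as.list(report$summary))
  if (!is.null(report$spatial_correlation)) {
    out$spatial_correlation <- report$spatial_correlation
    out$residualized_summary <- as.list(glance(report$residualized))
  }
  if (!is.null(report$clinical)) {
    out$clinical_summary <- as.list(glance(report$clinical))
  }
  out
}

#' Write an analysis report bundle to disk
#'
#' Writes the result maps as NIfTI images and a JSON summary embedding the
#' configuration, seed, package version and subject accounting. Identical
#' inputs and seed produce byte-identical output files.
#'
#' @param report An `lsm_report` from [run_appetite_analysis()] or
#'   [run_weight_analysis()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (report$mode == "appetite-map") {
    write_plsr_maps(report$result, dir, "appetite")
    if (!is.null(report$residualized)) {
      write_plsr_maps(report$residualized, dir, "appetite_residualized")
    }
  } else {
    write_prop_diff_maps(report$result, dir, "weight")
    if (!is.null(report$clinical)) {
      write_prop_diff_maps(report$clinical, dir, "weight_clinical")
    }
    write.csv(report$changes, file.path(dir, "weight_changes.csv"),
              row.names = FALSE)
  }
  jsonlite::write_json(report_json_payload(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.lsm_report <- function(x, ...) {
  cat(sprintf("<lsm_report> %s (lesionmapr %s, seed %d)\n", x$mode,
              x$version, x$seed))
  cat(sprintf("  subjects analysed: %d; voxels: %d\n",
              x$counts$n_analysed, x$counts$n_voxels_analysed))
  print(x$result)
  invisible(x)
}
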