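item18_levels <- c("0", "1a", "1b", "2a", "2b", "3a", "3b")
item18_scores <- c(0L, -1L, 1L, -2L, 2L, -3L, 3L)

#' Recode BDI-II item-18 appetite responses to a signed 7-point scale
#'
#' Item 18 ("Changes in Appetite") has seven response options: `0` (no
#' change), and severity levels 1-3 each in a decreased-appetite variant
#' (`1a`, `2a`, `3a`) and an increased-appetite variant (`1b`, `2b`, `3b`).
#' The decrease ("a") options are mapped to negative values, giving a signed
#' scale from -3 (no appetite at all) to +3 (craves food all the time), with
#' 0 meaning no change.
#'
#' @param item18_code Character vector of codes among
#'   `"0","1a","1b","2a","2b","3a","3b"`.
#' @return Integer vector of signed scores in `[-3, 3]`.
#' @examples
#' recode_appetite(c("0", "2a", "3b"))
#' @export
recode_appetite <- function(item18_code) {
  item18_code <- as.character(item18_code)
  idx <- match(item18_code, item18_levels)
  if (anyNA(idx)) {
    stopf("unknown item-18 code(s): %s",
          paste(unique(item18_code[is.na(idx)]), collapse = ", "))
  }
  item18_scores[idx]
}

#' Map signed appetite scores back to item-18 codes
#'
#' Inverse of [recode_appetite()]; used by the synthetic-cohort generator to
#' emit records in the raw questionnaire coding.
#'
#' @param score Integer vector in `[-3, 3]`.
#' @return Character vector of item-18 codes.
#' @export
appetite_item_code <- function(score) {
  if (any(!score %in% -3:3)) stopf("appetite scores must be integers in [-3, 3]")
  item18_levels[match(as.integer(score), item18_scores)]
}

#' Select one chronic-phase appetite score per subject
#'
#' Restricts to assessments taken in the chronic phase (at least
#' `chronic_min_days` after lesion onset) and, for subjects assessed more
#' than once, keeps the assessment with the maximum absolute recoded score —
#' the time point with the greatest reported change in appetite. Ties in
#' absolute score are broken by the earliest qualifying assessment. Subjects
#' with no chronic assessment are excluded and listed in the
#' `excluded_subjects` attribute.
#'
#' @param assessments A data frame with columns `subject_id`, `day_offset`
#'   (days since lesion onset), `item18_code`, `bdi_total`.
#' @param chronic_min_days Minimum day offset defining the chronic phase.
#' @return A tibble with one row per included subject: `subject_id`, `score`
#'   (signed, in `[-3, 3]`), `day_offset`, `bdi_total`,
#'   `bdi_total_minus_appetite` (total minus `|score|`). Attribute
#'   `excluded_subjects` holds ids with no chronic assessment.
#' @export
appetite_scores <- function(assessments, chronic_min_days = 90) {
  need <- c("subject_id", "day_offset", "item18_code", "bdi_total")
  if (!all(need %in% names(assessments))) {
    stopf("assessments must have columns: %s", paste(need, collapse = ", "))
  }
  assessments <- tibble::as_tibble(assessments)
  all_ids <- unique(assessments$subject_id)
  scored <- assessments |>
    dplyr::mutate(score = recode_appetite(.data$item18_code)) |>
    dplyr::filter(.data$day_offset >= chronic_min_days) |>
    dplyr::arrange(.data$subject_id, dplyr::desc(abs(.data$score)),
                   .data$day_offset) |>
    dplyr::distinct(.data$subject_id, .keep_all = TRUE) |>
    dplyr::transmute(
      subject_id = .data$subject_id,
      score = .data$score,
      day_offset = .data$day_offset,
      bdi_total = .data$bdi_total,
      bdi_total_minus_appetite = .data$bdi_total - abs(.data$score)
    )
  structure(scored,
            excluded_subjects = setdiff(all_ids, scored$subject_id))
}

#' Per-cent change in body weight
#'
#' @param w1 Baseline weight (kg), positive.
#' @param w2 Follow-up weight (kg).
#' @return `100 * (w2 - w1) / w1`. Scale-invariant: both weights in the same
#'   (positive) unit give the same result.
#' @examples
#' percent_weight_change(100, 92)
#' @export
percent_weight_change <- function(w1, w2) {
  if (any(w1 <= 0)) stopf("baseline weight w1 must be positive")
  100 * (w2 - w1) / w1
}

#' Binarize per-cent weight change into loss/gain groups
#'
#' Negative change codes -1 (weight loss), positive codes +1 (weight gain).
#' A change of exactly zero is excluded by default (coded `NA`), since the
#' analysis contrasts a loss group against a gain group; set
#' `zero_change = "gain"` to assign it to +1 instead.
#'
#' @param pct_change Numeric vector of per-cent weight changes.
#' @param zero_change `"exclude"` (default) or `"gain"`.
#' @return Integer vector of -1 / +1 / NA group codes.
#' @export
binarize_weight_change <- function(pct_change, zero_change = c("exclude", "gain")) {
  zero_change <- match.arg(zero_change)
  out <- ifelse(pct_change < 0, -1L, ifelse(pct_change > 0, 1L, NA_integer_))
  if (zero_change == "gain") out[!is.na(pct_change) & pct_change == 0] <- 1L
  out
}

select_pair_one <- function(day, weight, w1_max_day, w2_min_day, w2_max_day,
                            min_gap_days) {
  cand1 <- which(day <= w1_max_day)
  cand2 <- which(day >= w2_min_day & day <= w2_max_day)
  if (!length(cand1) || !length(cand2)) return(NULL)
  # W1 closest to onset (|day|, ties earlier); W2 latest in window. This
  # maximizes the elapsed gap, so a pair is found whenever one exists.
  i1 <- cand1[order(abs(day[cand1]), day[cand1])][1]
  cand2 <- cand2[day[cand2] - day[i1] >= min_gap_days & cand2 != i1]
  if (!length(cand2)) return(NULL)
  i2 <- cand2[which.max(day[cand2])]
  list(i1 = i1, i2 = i2)
}

#' Construct per-cent weight change from dated weight records
#'
#' For each subject, selects a baseline record W1 (taken no more than
#' `w1_max_day` days after lesion onset; pre-lesion records qualify) and a
#' follow-up record W2 (between `w2_min_day` and `w2_max_day` days after
#' onset), separated by at least `min_gap_days` days. When several records
#' qualify, W1 is the record closest to onset and W2 the latest in-window
#' record, maximizing the time for weight change to manifest. Subjects with
#' no valid pair are excluded and listed in the `excluded_subjects`
#' attribute.
#'
#' @param records Data frame with columns `subject_id`, `day_offset`,
#'   `weight_kg` (positive).
#' @param w1_max_day Latest allowed day for W1 (default 90).
#' @param w2_min_day,w2_max_day W2 window in days (defaults 90 and 1000).
#' @param min_gap_days Minimum days between W1 and W2 (default 30).
#' @param zero_change Passed to [binarize_weight_change()].
#' @return A tibble with one row per included subject: `subject_id`, `w1`,
#'   `w2`, `day_w1`, `day_w2`, `pct_change`, `group_code` (-1/+1/NA).
#' @export
weight_changes <- function(records, w1_max_day = 90, w2_min_day = 90,
                           w2_max_day = 1000, min_gap_days = 30,
                           zero_change = c("exclude", "gain")) {
  zero_change <- match.arg(zero_change)
  need <- c("subject_id", "day_offset", "weight_kg")
  if (!all(need %in% names(records))) {
    stopf("records must have columns: %s", paste(need, collapse = ", "))
  }
  if (any(records$weight_kg <= 0)) stopf("weights must be positive")
  records <- tibble::as_tibble(records)
  rows <- records |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_map(function(d, key) {
      p <- select_pair_one(d$day_offset, d$weight_kg, w1_max_day,
                           w2_min_day, w2_max_day, min_gap_days)
      if (is.null(p)) return(NULL)
      tibble::tibble(
        subject_id = key$subject_id,
        w1 = d$weight_kg[p$i1], w2 = d$weight_kg[p$i2],
        day_w1 = d$day_offset[p$i1], day_w2 = d$day_offset[p$i2],
        pct_change = percent_weight_change(d$weight_kg[p$i1],
                                           d$weight_kg[p$i2])
      )
    }) |>
    dplyr::bind_rows()
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(subject_id = character(), w1 = numeric(),
                           w2 = numeric(), day_w1 = numeric(),
                           day_w2 = numeric(), pct_change = numeric())
  }
  rows$group_code <- binarize_weight_change(rows$pct_change, zero_change)
  structure(rows,
            excluded_subjects = setdiff(unique(records$subject_id),
                                        rows$subject_id))
}

#' Restrict weight changes to the clinically significant subset
#'
#' Keeps subjects whose absolute per-cent weight change exceeds
#' `threshold_pct` (strictly), the conventional cut for clinically
#' significant weight change.
#'
#' @param changes Output of [weight_changes()] (any data frame with a
#'   `pct_change` column).
#' @param threshold_pct Threshold in per cent (default 5).
#' @return The filtered tibble.
#' @export
clinically_significant <- function(changes, threshold_pct = 5) {
  dplyr::filter(tibble::as_tibble(changes),
                abs(.data$pct_change) > threshold_pct)
}
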