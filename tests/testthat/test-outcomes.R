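test_that("item-18 recoding maps all seven options to the signed scale", {
  codes <- c("0", "1a", "1b", "2a", "2b", "3a", "3b")
  scores <- recode_appetite(codes)
  expect_identical(scores, c(0L, -1L, 1L, -2L, 2L, -3L, 3L))
  # odd symmetry: 'a' codes negative, 'b' codes positive, same magnitude
  expect_identical(recode_appetite(c("1a", "2a", "3a")),
                   -recode_appetite(c("1b", "2b", "3b")))
  # magnitude equals the printed severity digit
  expect_identical(abs(scores), c(0L, 1L, 1L, 2L, 2L, 3L, 3L))
  expect_error(recode_appetite("4a"), "unknown")
  # inverse mapping round-trips
  expect_identical(recode_appetite(appetite_item_code(-3:3)), -3:3)
})

test_that("chronic assessment selection keeps the maximum |score|", {
  tbl <- function(...) {
    rows <- list(...)
    tibble::tibble(
      subject_id = vapply(rows, `[[`, character(1), 1),
      day_offset = as.numeric(vapply(rows, `[[`, character(1), 2)),
      item18_code = vapply(rows, `[[`, character(1), 3),
      bdi_total = as.numeric(vapply(rows, `[[`, character(1), 4)))
  }
  # max |score| wins regardless of order
  a <- appetite_scores(tbl(c("s1", "100", "1a", "10"),
                           c("s1", "400", "2b", "12")))
  expect_equal(a$score, 2L)
  expect_equal(a$bdi_total_minus_appetite, 10)

  # singleton passes through
  b <- appetite_scores(tbl(c("s1", "95", "3a", "20")))
  expect_equal(b$score, -3L)

  # |score| tie broken by the earliest assessment, in either input order
  t1 <- tbl(c("s1", "100", "2b", "8"), c("s1", "200", "2a", "8"))
  t2 <- t1[2:1, ]
  expect_equal(appetite_scores(t1)$score, 2L)
  expect_equal(appetite_scores(t2)$score, 2L)

  # sub-chronic assessments are invisible; all-subchronic subjects excluded
  c1 <- appetite_scores(tbl(c("s1", "10", "3a", "9"),
                            c("s1", "120", "1b", "9"),
                            c("s2", "30", "2a", "7")))
  expect_equal(c1$subject_id, "s1")
  expect_equal(c1$score, 1L)
  expect_equal(attr(c1, "excluded_subjects"), "s2")
})

test_that("per-cent weight change is exact and scale invariant", {
  expect_equal(percent_weight_change(100, 92), -8)
  expect_equal(percent_weight_change(80, 84), 5)
  expect_equal(percent_weight_change(63.7, 63.7), 0)
  withr::with_seed(1, {
    w1 <- runif(20, 40, 150); w2 <- runif(20, 40, 150); c0 <- runif(20, .1, 9)
    expect_equal(percent_weight_change(c0 * w1, c0 * w2),
                 percent_weight_change(w1, w2))
  })
  expect_error(percent_weight_change(0, 50), "positive")
})

test_that("W1/W2 selection enforces the three window rules", {
  rec <- function(days, weights = seq(80, by = 1, length.out = length(days))) {
    tibble::tibble(subject_id = "s1", day_offset = days, weight_kg = weights)
  }
  # valid pair: day 10 and day 200, gap 190
  ok <- weight_changes(rec(c(10, 200), c(100, 92)))
  expect_equal(nrow(ok), 1)
  expect_equal(ok$day_w1, 10)
  expect_equal(ok$day_w2, 200)
  expect_equal(ok$pct_change, -8)
  expect_equal(ok$group_code, -1L)

  # gap below 30 days: excluded
  short <- weight_changes(rec(c(80, 100)))
  expect_equal(nrow(short), 0)
  expect_equal(attr(short, "excluded_subjects"), "s1")

  # W2 beyond 1000 days: excluded
  late <- weight_changes(rec(c(10, 1200)))
  expect_equal(nrow(late), 0)

  # several candidates: W1 closest to onset, W2 latest in window
  multi <- weight_changes(rec(c(5, 60, 150, 900, 1100)))
  expect_equal(multi$day_w1, 5)
  expect_equal(multi$day_w2, 900)
})

test_that("any selected pair satisfies the windows on random record sets", {
  withr::with_seed(2024, {
    for (rep in 1:50) {
      n <- sample(2:6, 1)
      rec <- tibble::tibble(subject_id = "s",
                            day_offset = sample(0:1400, n),
                            weight_kg = runif(n, 45, 140))
      ch <- weight_changes(rec)
      if (nrow(ch) == 1) {
        expect_lte(ch$day_w1, 90)
        expect_gte(ch$day_w2, 90)
        expect_lte(ch$day_w2, 1000)
        expect_gte(ch$day_w2 - ch$day_w1, 30)
        expect_equal(ch$pct_change,
                     percent_weight_change(ch$w1, ch$w2))
      } else {
        # oracle: exhaustive pair search finds nothing either
        found <- FALSE
        for (i in seq_len(n)) for (j in seq_len(n)) {
          if (i != j && rec$day_offset[i] <= 90 &&
              rec$day_offset[j] >= 90 && rec$day_offset[j] <= 1000 &&
              rec$day_offset[j] - rec$day_offset[i] >= 30) found <- TRUE
        }
        expect_false(found)
      }
    }
  })
})

test_that("binarization maps sign to group and zero to the configured rule", {
  expect_identical(binarize_weight_change(c(-8, 5, 0)),
                   c(-1L, 1L, NA_integer_))
  expect_identical(binarize_weight_change(0, zero_change = "gain"), 1L)
  # exclusion of zero leaves both group counts unchanged
  x <- c(-3, -1, 0, 2, 4)
  g <- binarize_weight_change(x)
  expect_equal(sum(g == -1L, na.rm = TRUE), 2)
  expect_equal(sum(g == 1L, na.rm = TRUE), 2)
})

test_that("the clinically significant subset keeps |change| above threshold", {
  ch <- tibble::tibble(subject_id = letters[1:4],
                       pct_change = c(-6, -4, 5.5, 3))
  expect_equal(clinically_significant(ch)$pct_change, c(-6, 5.5))
  expect_equal(nrow(clinically_significant(ch, threshold_pct = 10)), 0)
  expect_equal(nrow(clinically_significant(ch, threshold_pct = 0)), 4)
})
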