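two_group_stack <- function(n = 8, grid = toy_grid(), seed = 17) {
  masks <- random_masks(n, grid, seed = seed)
  stack <- stack_cohort(masks)
  groups <- rep(c(-1L, 1L), length.out = n)
  list(masks = masks, stack = stack, groups = groups)
}

test_that("group proportions and the difference map match per-voxel loops", {
  d <- two_group_stack()
  voxels <- which(d$stack$analysis_mask)
  expect_equal(unname(proportional_overlap(d$stack, d$groups == 1L)),
               oracle_prop(d$masks, d$groups == 1L, voxels))
  expect_equal(unname(proportional_difference(d$stack, d$groups)),
               oracle_prop(d$masks, d$groups == 1L, voxels) -
                 oracle_prop(d$masks, d$groups == -1L, voxels))
})

test_that("the difference map hits its analytic extremes", {
  grid <- toy_grid(c(2, 2, 1))
  mk <- function(where, id) {
    arr <- array(0, grid$dims); arr[where] <- 1
    lesion_mask(arr, grid, id)
  }
  # gain subjects all lesion voxel 1, loss subjects all lesion voxel 2
  stack <- stack_cohort(list(mk(1, "g1"), mk(1, "g2"), mk(2, "l1"), mk(2, "l2")))
  D <- proportional_difference(stack, c(1, 1, -1, -1))
  expect_equal(unname(D[1:2]), c(1, -1))
  expect_true(all(D >= -1 & D <= 1))
})

test_that("swapping the group labels negates the difference map", {
  d <- two_group_stack(seed = 23)
  D1 <- proportional_difference(d$stack, d$groups)
  D2 <- proportional_difference(d$stack, -d$groups)
  expect_equal(D2, -D1)
})

test_that("group label validation rejects malformed inputs", {
  d <- two_group_stack(n = 4)
  expect_error(proportional_difference(d$stack, c(1, 1, 1, 1)),
               "must be nonempty")
  expect_error(proportional_difference(d$stack, c(0, 1, -1, 1)), "-1 or \\+1")
  expect_error(proportional_difference(d$stack, c(1, -1)), "one -1/\\+1 label")
})

test_that("uncorrected voxel p-values match the stored-permutation oracle", {
  d <- two_group_stack(n = 6, grid = toy_grid(c(3, 3, 2)), seed = 31)
  voxels <- which(d$stack$analysis_mask)
  B <- 60
  null <- permute_prop_diff(d$stack, d$groups, n_permutations = B,
                            voxel_extent = 1, seed = 7)
  # reconstruct the same permutations from the same substream and hand them
  # to a full double loop over permutations and voxels
  perms <- withr::with_seed(derive_seed(7, 1L), {
    vapply(seq_len(B), function(b) sample(d$groups), integer(6))
  })
  expect_equal(unname(uncorrected_voxel_p(null)),
               oracle_uncorrected_p(d$masks, d$groups, voxels, perms))
  # and the observed map the null carries is the real observed map
  expect_equal(null$D_obs, proportional_difference(d$stack, d$groups))
})

test_that("voxel_extent = 1 reduces to the max-statistic test", {
  d <- two_group_stack(n = 8, seed = 41)
  B <- 99
  null <- permute_prop_diff(d$stack, d$groups, n_permutations = B,
                            voxel_extent = 1, seed = 3)
  perms <- withr::with_seed(derive_seed(3, 1L), {
    vapply(seq_len(B), function(b) sample(d$groups), integer(8))
  })
  voxels <- which(d$stack$analysis_mask)
  max_null <- vapply(seq_len(B), function(b) {
    max(abs(oracle_D(d$masks, perms[, b], voxels)))
  }, numeric(1))
  expect_equal(unname(null$vth_largest), max_null)
})

test_that("the critical value is the right order statistic of the null", {
  d <- two_group_stack(n = 10, grid = toy_grid(c(6, 6, 6)), seed = 5)
  B <- 199
  v <- 20
  null <- permute_prop_diff(d$stack, d$groups, n_permutations = B,
                            voxel_extent = v, seed = 9)
  # oracle: sort each permuted |D| map in full and take position v
  perms <- withr::with_seed(derive_seed(9, 1L), {
    vapply(seq_len(B), function(b) sample(d$groups), integer(10))
  })
  voxels <- which(d$stack$analysis_mask)
  vth <- vapply(seq_len(B), function(b) {
    sort(abs(oracle_D(d$masks, perms[, b], voxels)), decreasing = TRUE)[v]
  }, numeric(1))
  expect_equal(unname(null$vth_largest), vth)

  fwe <- continuous_fwe_threshold(null, alpha_fwe = 0.05)
  k <- min(ceiling(0.95 * (B + 1)), B)
  expect_equal(fwe$crit_value, sort(vth)[k])
  # survivors use the tie-aware corrected p, never anticonservative
  s_obs <- abs(null$D_obs)
  p_ref <- vapply(s_obs, function(s) (1 + sum(vth >= s)) / (B + 1), numeric(1))
  expect_equal(fwe$survivors, p_ref <= 0.05)
  # observed-extent verdict consistent with its corrected p
  expect_equal(fwe$extent_pass, fwe$fwe_p <= 0.05)
})

test_that("an over-large voxel extent is refused up front", {
  d <- two_group_stack(n = 4)
  Vp <- sum(d$stack$analysis_mask)
  expect_error(permute_prop_diff(d$stack, d$groups, 10, voxel_extent = Vp + 1),
               "no extent-passing result is possible")
  expect_error(permute_prop_diff(d$stack, d$groups, 10, voxel_extent = 0),
               ">= 1")
})

test_that("one-sided alternatives use signed D and mirror each other", {
  d <- two_group_stack(n = 8, seed = 13)
  ng <- permute_prop_diff(d$stack, d$groups, 50, 1, "greater", seed = 2)
  nl <- permute_prop_diff(d$stack, -d$groups, 50, 1, "less", seed = 2)
  # flipping both the labels and the tail gives identical statistics
  expect_equal(ng$vth_largest, nl$vth_largest)
  expect_equal(ng$D_obs, -nl$D_obs)
  expect_equal(ng$exceed_count, nl$exceed_count)
})

test_that("26-connectivity component sizes are correct on known shapes", {
  dims <- c(5, 5, 5)
  lin <- function(i, j, k) i + (j - 1) * 5 + (k - 1) * 25
  # a 2x2 plaquette, a diagonal pair (26-connected), and an isolated voxel
  vox <- c(lin(1, 1, 1), lin(2, 1, 1), lin(1, 2, 1), lin(2, 2, 1),
           lin(4, 4, 4), lin(5, 5, 5),
           lin(1, 5, 5))
  sizes <- label_components(vox, dims)
  expect_equal(sort(sizes), c(1L, 2L, 4L))
  expect_equal(label_components(integer(0), dims), integer(0))
})

test_that("the full prop_diff_map pipeline is coherent and deterministic", {
  d <- two_group_stack(n = 10, grid = toy_grid(c(6, 6, 6)), seed = 19)
  m1 <- prop_diff_map(d$stack, d$groups, n_permutations = 99, voxel_extent = 5,
                      seed = 4)
  m2 <- prop_diff_map(d$stack, d$groups, n_permutations = 99, voxel_extent = 5,
                      seed = 4)
  expect_identical(m1$d, m2$d)
  expect_identical(m1$survivors, m2$survivors)
  expect_identical(m1$crit_value, m2$crit_value)
  # d decomposes into the two group proportions
  expect_equal(m1$d, m1$p_plus - m1$p_minus)
  # uncorrected p reported only on survivors
  expect_true(all(is.na(m1$uncorrected_p[!m1$survivors])))
  expect_true(all(!is.na(m1$uncorrected_p[m1$survivors])))
  g <- glance(m1)
  expect_equal(g$n_survivors, sum(m1$survivors))
  td <- tidy(m1)
  expect_equal(nrow(td), length(m1$d))
  # cluster extent rule runs and is no more permissive than global
  mc <- prop_diff_map(d$stack, d$groups, n_permutations = 99, voxel_extent = 5,
                      extent_rule = "cluster", seed = 4)
  expect_true(!mc$extent_pass || m1$extent_pass)
})
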