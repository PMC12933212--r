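small_cfg <- function(...) {
  sim_config(grid_dims = c(10, 10, 10), n_subjects = 8,
             volume_range = c(20, 60), seed = 42, ...)
}

test_that("generated lesions hit the exact requested volume range", {
  masks <- generate_lesions(small_cfg())
  vols <- vapply(masks, `[[`, integer(1), "volume")
  expect_true(all(vols >= 20 & vols <= 60))
  expect_equal(vapply(masks, `[[`, character(1), "subject_id"),
               sprintf("S%03d", 1:8))
  # volume equals the number of lesioned voxels, by definition of the mask
  for (m in masks) expect_equal(sum(m$data), m$volume)
})

test_that("every generated lesion is a single 6-connected component", {
  masks <- generate_lesions(small_cfg())
  for (m in masks) {
    expect_equal(oracle_n_components6(m$data), 1L)
  }
  # also under a custom uniform spatial prior
  cfg_u <- sim_config(grid_dims = c(8, 8, 8), n_subjects = 5,
                      volume_range = c(10, 30),
                      spatial_prior = array(1, c(8, 8, 8)), seed = 3)
  for (m in generate_lesions(cfg_u)) {
    expect_equal(oracle_n_components6(m$data), 1L)
  }
})

test_that("grow_lesion reaches exactly the requested volume when it fits", {
  withr::with_seed(9, {
    for (vol in c(1, 7, 50, 200)) {
      idx <- grow_lesion(c(8, 8, 8), vol, seed_voxel = 1L)
      expect_length(idx, vol)
      expect_equal(anyDuplicated(idx), 0L)
    }
  })
  expect_error(grow_lesion(c(2, 2, 2), 9, 1L), "exceeds the grid")
})

test_that("cohort generation is reproducible and substream-stable", {
  m1 <- generate_lesions(small_cfg())
  m2 <- generate_lesions(small_cfg())
  for (s in seq_along(m1)) expect_identical(m1[[s]]$data, m2[[s]]$data)
  # enlarging the cohort never changes earlier subjects
  big <- generate_lesions(sim_config(grid_dims = c(10, 10, 10),
                                     n_subjects = 12,
                                     volume_range = c(20, 60), seed = 42))
  for (s in 1:8) expect_identical(big[[s]]$data, m1[[s]]$data)
  # full cohorts with outcomes are reproducible too
  c1 <- simulate_cohort(small_cfg())
  c2 <- simulate_cohort(small_cfg())
  expect_identical(c1$stack$X, c2$stack$X)
  expect_identical(c1$outcomes, c2$outcomes)
})

test_that("noiseless appetite outcomes follow the latent rule exactly", {
  grid10 <- voxel_grid(c(10, 10, 10))
  truth <- truth_ball(grid10, radius = 2.5)
  # lesions disjoint from the truth region -> zero load -> score 0
  corner_prior <- array(0, c(10, 10, 10)); corner_prior[1, 1, 1] <- 1
  cfg0 <- sim_config(grid_dims = c(10, 10, 10), n_subjects = 5,
                     volume_range = c(5, 10), spatial_prior = corner_prior,
                     truth_region = truth, noise_sd = 0, seed = 7)
  coh0 <- simulate_cohort(cfg0)
  loads <- vapply(coh0$masks, function(m) sum(m$data[truth]), numeric(1))
  expect_true(all(loads == 0))
  expect_true(all(coh0$outcomes$item18_code == "0"))

  # a huge effect saturates every truth-lesioned subject at -3
  centre_prior <- array(0, c(10, 10, 10)); centre_prior[5, 5, 5] <- 1
  cfg3 <- sim_config(grid_dims = c(10, 10, 10), n_subjects = 5,
                     volume_range = c(40, 60), spatial_prior = centre_prior,
                     truth_region = truth, effect_size = 100, noise_sd = 0,
                     seed = 7)
  coh3 <- simulate_cohort(cfg3)
  expect_true(all(recode_appetite(coh3$outcomes$item18_code) == -3L))

  # scores match the documented discretization of the latent value
  cfg1 <- sim_config(grid_dims = c(10, 10, 10), n_subjects = 10,
                     volume_range = c(20, 80), truth_region = truth,
                     effect_size = 4, noise_sd = 0, seed = 11)
  coh1 <- simulate_cohort(cfg1)
  load1 <- vapply(coh1$masks, function(m)
    sum(m$data[truth]) / sqrt(m$volume), numeric(1))
  expected <- pmax(pmin(as.integer(round(-4 * load1)), 3L), -3L)
  expect_identical(recode_appetite(coh1$outcomes$item18_code), expected)
  # BDI total is never smaller than the appetite contribution
  expect_true(all(coh1$outcomes$bdi_total >=
                    abs(recode_appetite(coh1$outcomes$item18_code))))
})

test_that("weight records always admit a valid W1/W2 pair with the right change", {
  cfg <- sim_config(grid_dims = c(10, 10, 10), n_subjects = 12,
                    volume_range = c(20, 60), outcome = "weight", seed = 5)
  coh <- simulate_cohort(cfg)
  ch <- weight_changes(coh$outcomes)
  expect_equal(nrow(ch), 12)
  expect_true(all(ch$day_w1 <= 90))
  expect_true(all(ch$day_w2 >= 120 & ch$day_w2 <= 1000))
  expect_true(all(ch$day_w2 - ch$day_w1 >= 30))
  expect_true(all(ch$pct_change > -80 - 1e-9))

  # zero effect, pure noise: both outcome groups occur in a moderate cohort
  cfg0 <- sim_config(grid_dims = c(10, 10, 10), n_subjects = 30,
                     volume_range = c(20, 60), outcome = "weight",
                     effect_size = 0, noise_sd = 5, seed = 6)
  ch0 <- weight_changes(simulate_cohort(cfg0)$outcomes)
  expect_gt(sum(ch0$group_code == 1L, na.rm = TRUE), 0)
  expect_gt(sum(ch0$group_code == -1L, na.rm = TRUE), 0)

  # noiseless, truth-covering lesions: every subject loses weight
  centre_prior <- array(0, c(10, 10, 10)); centre_prior[5, 5, 5] <- 1
  truth <- truth_ball(voxel_grid(c(10, 10, 10)), radius = 2)
  cfgl <- sim_config(grid_dims = c(10, 10, 10), n_subjects = 6,
                     volume_range = c(60, 80), spatial_prior = centre_prior,
                     truth_region = truth, outcome = "weight",
                     effect_size = 50, noise_sd = 0, seed = 8)
  chl <- weight_changes(simulate_cohort(cfgl)$outcomes)
  expect_true(all(chl$group_code == -1L))
})

test_that("configuration validation catches impossible requests", {
  expect_error(sim_config(grid_dims = c(3, 3, 3), volume_range = c(5, 100)),
               "exceeds grid capacity")
  expect_error(sim_config(truth_region = c(1, 99999)), "outside the grid")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(generate_lesions(
    sim_config(grid_dims = c(4, 4, 4), n_subjects = 2,
               volume_range = c(1, 2),
               spatial_prior = array(-1, c(4, 4, 4)))),
    "non-negative")
})

test_that("the written cohort reloads into the identical analysis inputs", {
  cfg <- sim_config(grid_dims = c(8, 8, 8), n_subjects = 5,
                    volume_range = c(10, 30), seed = 21)
  coh <- simulate_cohort(cfg)
  d <- withr::local_tempdir()
  write_cohort(coh, d)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  expect_true(file.exists(file.path(d, "behaviour.csv")))
  expect_true(file.exists(file.path(d, "sim_config.json")))
  stack <- read_cohort(file.path(d, "manifest.csv"), coh$stack$grid)
  expect_identical(stack$X, coh$stack$X)
  beh <- read.csv(file.path(d, "behaviour.csv"),
                  colClasses = c(item18_code = "character"))
  expect_equal(tibble::as_tibble(beh), coh$outcomes)
})
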