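test_that("the default truth is internally consistent", {
  truth <- default_truth()
  for (s in names(truth$sites)) {
    pr <- truth$sites[[s]]$profile
    expect_equal(sum(pr$swallowed_by) + pr$spat_out + pr$undispersed, 1,
                 tolerance = 1e-12)
  }
  # truth models pass all model invariants and have sane recruitment
  for (s in names(truth$sites)) {
    m <- truth_model(truth, s)
    rs <- recruitment_success(m)$rs_percent
    expect_gt(rs, 0)
    expect_lt(rs, 100)
  }
})

test_that("generators are deterministic under a fixed seed", {
  truth <- default_truth()
  expect_identical(simulate_focal_observations(truth, "intact", 500, 3),
                   simulate_focal_observations(truth, "intact", 500, 3))
  expect_identical(simulate_germination_trials(truth, rng_seed = 4),
                   simulate_germination_trials(truth, rng_seed = 4))
  expect_identical(simulate_dispersal_distances(truth, "muriqui", 100, 5),
                   simulate_dispersal_distances(truth, "muriqui", 100, 5))
  expect_identical(simulate_survival_experiment(truth, "intact", rng_seed = 6),
                   simulate_survival_experiment(truth, "intact", rng_seed = 6))
  expect_identical(simulate_camera_traps(truth, "intact", 300, 7),
                   simulate_camera_traps(truth, "intact", 300, 7))
  # and independent of the global RNG state
  set.seed(1); a <- simulate_focal_observations(truth, "intact", 200, 9)
  set.seed(999); b <- simulate_focal_observations(truth, "intact", 200, 9)
  expect_identical(a, b)
})

test_that("degenerate generator settings produce their exact limits", {
  truth <- default_truth()
  # single-pathway profile: every fruit is swallowed by that disperser
  truth1 <- truth
  truth1$sites$intact$profile$swallowed_by <- c(jacutinga = 1)
  truth1$sites$intact$profile$spat_out <- 0
  truth1$sites$intact$profile$undispersed <- 0
  rec <- simulate_focal_observations(truth1, "intact", 500, 2)
  expect_equal(sum(rec$n_swallowed[rec$actor == "jacutinga"]), 500)
  expect_equal(sum(rec$n_spat) + sum(rec$n_dropped), 0)
  # certain and impossible germination
  truth2 <- truth
  truth2$germination[] <- 1
  g <- simulate_germination_trials(truth2, rng_seed = 3)
  expect_true(all(g$n_germinated == g$n_sown))
  truth2$germination[] <- 0
  g <- simulate_germination_trials(truth2, rng_seed = 3)
  expect_true(all(g$n_germinated == 0))
  # zero-spread kernel collapses onto the mean
  truth3 <- truth
  truth3$kernels$howler$sd <- 0
  s <- simulate_dispersal_distances(truth3, "howler", 50, 8)
  expect_true(all(s$distances_m == 9.7))
  # zero baseline survival kills every seed
  truth4 <- truth
  truth4$sites$intact$escape <- list(base_5m = 0, slope = 0)
  surv <- simulate_survival_experiment(truth4, "intact", rng_seed = 2)
  expect_true(all(surv$n_surviving == 0))
  # parameters implying survival > 1 are rejected
  truth5 <- truth
  truth5$sites$intact$escape <- list(base_5m = 0.5, slope = 0.05)
  expect_error(simulate_survival_experiment(truth5, "intact", rng_seed = 2),
               class = "seedfate_validation_error")
  # silent cameras
  truth6 <- truth
  truth6$sites$intact$visitation[] <- 0
  cams <- simulate_camera_traps(truth6, "intact", 1000, 4)
  expect_true(all(cams$n_visits == 0))
})

test_that("generators recover their own parameters at large n", {
  truth <- default_truth()
  # fate fractions within 3 binomial SE
  rec <- simulate_focal_observations(truth, "intact", 10000, rng_seed = 31)
  pr <- seed_fate_profile(rec, "intact")
  for (d in names(truth$sites$intact$profile$swallowed_by)) {
    p0 <- truth$sites$intact$profile$swallowed_by[[d]]
    se <- sqrt(p0 * (1 - p0) / 10000)
    expect_lt(abs(removal_probability(pr, d) - p0), 3 * se + 1e-12)
  }
  # kernel moments within 3 SE of the target
  s <- simulate_dispersal_distances(truth, "muriqui", 50000, rng_seed = 32)
  ks <- kernel_summary(s)
  expect_lt(abs(ks$mean_m - 59.7), 3 * 35.7 / sqrt(50000))
  # germination rate within 3 empirical SE (block effects inflate binomial noise)
  g <- simulate_germination_trials(truth, n_blocks = 200, rng_seed = 33,
                                   treatments = "defecated_howler")
  est <- germination_rate(g, "defecated_howler")
  se <- sd(g$n_germinated / g$n_sown) / sqrt(200)
  expect_lt(abs(est$rate - 0.75), 3 * se)
  # camera-trap rates: recovery and the between-site rodent release ratio
  cams_int <- simulate_camera_traps(truth, "intact", 10000, rng_seed = 34)
  cams_mod <- simulate_camera_traps(truth, "moderate", 10000, rng_seed = 35)
  r_int <- visitation_rate(cams_int, "small_rodent", "intact")
  r_mod <- visitation_rate(cams_mod, "small_rodent", "moderate")
  expect_lt(abs(r_int - 70), 3 * sqrt(70 / 100 * 10000) / 100)
  ratio_true <- 70 / 5
  expect_lt(abs(r_int / r_mod - ratio_true), 0.15 * ratio_true)
})

test_that("a written dataset is complete, readable and seed-stable", {
  truth <- default_truth()
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  paths_a <- write_synthetic_dataset(truth, dir_a, n_fruits = 300,
                                     n_distances = 120, n_per_distance = 20,
                                     rng_seed = 5)
  paths_b <- write_synthetic_dataset(truth, dir_b, n_fruits = 300,
                                     n_distances = 120, n_per_distance = 20,
                                     rng_seed = 5)
  expect_true(all(file.exists(paths_a)))
  for (f in setdiff(names(paths_a), "truth")) {
    expect_identical(readLines(paths_a[[f]]), readLines(paths_b[[f]]))
  }
  focal <- read_focal_records(paths_a[["focal"]])
  expect_equal(sum(focal$n_swallowed + focal$n_spat + focal$n_dropped),
               3 * 300)
  surv <- read_survival_records(paths_a[["survival"]])
  expect_equal(sum(surv$n_placed), 3 * 2 * 4 * 20)  # sites x years x classes
})
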