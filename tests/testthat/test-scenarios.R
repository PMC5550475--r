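toy_base <- function() {
  site_recruitment_model("intact", list(
    seed_fate_pathway("A", 0.3, 0.5, distance_kernel(rep(0.25, 4))),
    seed_fate_pathway("B", 0.4, 0.8,
                      distance_kernel(c(0.3, rep(0, 8), 0.7))),
    seed_fate_pathway("spat_out", 0.2, 0.6, degenerate_kernel()),
    seed_fate_pathway("undispersed", 0.1, 0.4, degenerate_kernel())
  ), new_escape_curve(c(0.1, 0.2, 0.3, 0.4), site = "intact"))
}

profile_B_only <- function() {
  structure(list(site = "other", swallowed_by = c(B = 0.5), spat_out = 0.3,
                 undispersed = 0.2, n_fruits = 1000L),
            class = "seed_fate_profile")
}

test_that("removing a disperser reallocates its mass to the undispersed pathway", {
  m <- toy_base()
  m2 <- remove_disperser(m, "A")
  p <- removal_fractions(m2)
  expect_equal(unname(p["A"]), 0)
  expect_equal(unname(p["undispersed"]), 0.1 + 0.3)
  expect_equal(unname(p["B"]), 0.4)  # others untouched
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # other components unchanged
  expect_equal(m2$pathways$B$germination_prob, 0.8)
  # removing an absent disperser is a no-op
  expect_identical(remove_disperser(m, "tapir"), m)
  # removing a zero-removal disperser leaves recruitment unchanged
  m0 <- remove_disperser(remove_disperser(m, "A"), "A")
  expect_equal(recruitment_success(m0)$rs_percent,
               recruitment_success(remove_disperser(m, "A"))$rs_percent)
})

test_that("compensation rewires removal fractions from an observed profile", {
  m <- toy_base()
  m2 <- remove_disperser(m, "A", profile_B_only())
  p <- removal_fractions(m2)
  expect_equal(unname(p[c("A", "B", "spat_out", "undispersed")]),
               c(0, 0.5, 0.3, 0.2))
  # germination and kernels of the remaining pathways keep intact-site values
  expect_equal(m2$pathways$B$germination_prob, 0.8)
  expect_equal(m2$pathways$B$kernel$probs, m$pathways$B$kernel$probs)
  # a profile still containing the removed disperser is inconsistent
  bad <- profile_B_only()
  bad$swallowed_by <- c(A = 0.2, B = 0.3)
  expect_error(remove_disperser(m, "A", bad),
               class = "seedfate_compensation_error")
  # a profile naming a disperser the model never had is an error
  stray <- profile_B_only()
  stray$swallowed_by <- c(B = 0.3, C = 0.2)
  expect_error(remove_disperser(m, "A", stray),
               class = "seedfate_compensation_error")
})

test_that("predator scenarios substitute the escape curve linearly", {
  m <- toy_base()
  rs <- recruitment_success(m)$rs_percent
  expect_equal(recruitment_success(
    apply_predator_scenario(m, m$escape))$rs_percent, rs)
  halved <- new_escape_curve(m$escape$survival / 2)
  expect_equal(recruitment_success(
    apply_predator_scenario(m, halved))$rs_percent, rs / 2, tolerance = 1e-12)
  zero <- new_escape_curve(rep(0, 4))
  expect_equal(recruitment_success(
    apply_predator_scenario(m, zero))$rs_percent, 0)
})

test_that("relative change follows the reference convention", {
  expect_equal(relative_change(9, 9), 0)
  expect_equal(relative_change(4.5, 9), -50)
  expect_error(relative_change(5, 0), class = "seedfate_validation_error")
})

test_that("every grid cell equals an independently derived recruitment value", {
  m <- toy_base()
  curves <- list(t1 = new_escape_curve(c(0.1, 0.2, 0.3, 0.4)),
                 t2 = new_escape_curve(c(0.05, 0.1, 0.15, 0.2)))
  grid <- scenario_grid(m, c("A", "B"), curves,
                        compensation_profiles = list(B = profile_B_only()))

  # independent hand derivation: class masses worked out from the bin
  # midpoints (A: bins 2.5/7.5/12.5/17.5 m -> classes 1,1,2,2;
  # B: 0.3 at 2.5 m -> class 1, 0.7 at 47.5 m -> class 4)
  cell_rs <- function(P, Tm) {
    mass <- rbind(A = c(0.5, 0.5, 0, 0), B = c(0.3, 0, 0, 0.7),
                  spat_out = c(1, 0, 0, 0), undispersed = c(1, 0, 0, 0))
    G <- c(A = 0.5, B = 0.8, spat_out = 0.6, undispersed = 0.4)
    sum(vapply(names(P), function(s) {
      100 * P[[s]] * G[[s]] * sum(mass[s, ] * Tm)
    }, numeric(1)))
  }
  P_full <- c(A = 0.3, B = 0.4, spat_out = 0.2, undispersed = 0.1)
  P_noA <- c(A = 0, B = 0.4, spat_out = 0.2, undispersed = 0.4)
  P_noA_comp <- c(A = 0, B = 0.5, spat_out = 0.3, undispersed = 0.2)
  P_none <- c(A = 0, B = 0, spat_out = 0.2, undispersed = 0.8)
  for (scen in c("t1", "t2")) {
    Tm <- curves[[scen]]$survival
    pick <- function(label, comp) {
      grid$rs_percent[grid$predator_scenario == scen &
                        grid$dispersers_present == label &
                        grid$compensation == comp]
    }
    expect_equal(pick("A+B", FALSE), cell_rs(P_full, Tm), tolerance = 1e-9)
    expect_equal(pick("B", FALSE), cell_rs(P_noA, Tm), tolerance = 1e-9)
    expect_equal(pick("B", TRUE), cell_rs(P_noA_comp, Tm), tolerance = 1e-9)
    expect_equal(pick("none", FALSE), cell_rs(P_none, Tm), tolerance = 1e-9)
    # deltas follow the two reference conventions exactly
    base_ref <- cell_rs(P_full, curves$t1$survival)
    base_own <- cell_rs(P_full, Tm)
    got <- grid[grid$predator_scenario == scen &
                  grid$dispersers_present == "none" & !grid$compensation, ]
    expect_equal(got$delta_vs_reference_percent,
                 100 * (cell_rs(P_none, Tm) - base_ref) / base_ref,
                 tolerance = 1e-9)
    expect_equal(got$delta_vs_scenario_baseline_percent,
                 100 * (cell_rs(P_none, Tm) - base_own) / base_own,
                 tolerance = 1e-9)
  }
})

test_that("cumulative removal commutes and conserves mass", {
  m <- toy_base()
  ab <- remove_disperser(remove_disperser(m, "A"), "B")
  ba <- remove_disperser(remove_disperser(m, "B"), "A")
  expect_equal(removal_fractions(ab), removal_fractions(ba), tolerance = 1e-12)
  expect_equal(recruitment_success(ab)$rs_percent,
               recruitment_success(ba)$rs_percent, tolerance = 1e-12)
  curves <- list(t1 = new_escape_curve(c(0.1, 0.2, 0.3, 0.4)))
  grid <- scenario_grid(m, c("A", "B"), curves)
  expect_true(all(grid$rs_percent >= 0 & grid$rs_percent <= 100))
})

test_that("grid shape: baselines only without losses, flagged fallback cells", {
  m <- toy_base()
  curves <- list(t1 = new_escape_curve(rep(0.2, 4)),
                 t2 = new_escape_curve(rep(0.1, 4)),
                 t3 = new_escape_curve(rep(0.05, 4)))
  empty <- scenario_grid(m, character(0), curves)
  expect_equal(nrow(empty), 3)
  expect_true(all(empty$n_lost == 0))
  # no compensation profile for {B}: the compensated cell falls back,
  # flagged as unavailable
  grid <- scenario_grid(m, c("A", "B"), curves)
  fallback <- grid[grid$dispersers_present == "B" & grid$compensation, ]
  expect_true(all(!fallback$compensation_available))
  plain <- grid[grid$dispersers_present == "B" & !grid$compensation, ]
  expect_equal(fallback$rs_percent, plain$rs_percent)
  expect_error(scenario_grid(m, c("A", "tapir"), curves),
               class = "seedfate_validation_error")
})
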