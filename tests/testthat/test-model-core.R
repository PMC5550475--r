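test_that("constructors enforce the seed-fate invariants", {
  expect_error(distance_kernel(c(0.5, 0.4)), class = "seedfate_validation_error")
  expect_error(distance_kernel(c(-0.1, 1.1)), class = "seedfate_validation_error")
  expect_error(seed_fate_pathway("a", 1.2, 0.5, degenerate_kernel()),
               class = "seedfate_validation_error")
  expect_error(new_escape_curve(c(0.5, 0.5, 0.5, 1.5)),
               class = "seedfate_validation_error")
  # removal fractions must cover the whole crop
  pw <- list(seed_fate_pathway("a", 0.5, 0.5, degenerate_kernel()),
             seed_fate_pathway("undispersed", 0.4, 0.5, degenerate_kernel()))
  expect_error(site_recruitment_model("s", pw, new_escape_curve(rep(0.5, 4))),
               class = "seedfate_validation_error")
  # duplicate labels
  pw2 <- list(seed_fate_pathway("a", 0.5, 0.5, degenerate_kernel()),
              seed_fate_pathway("a", 0.5, 0.5, degenerate_kernel()))
  expect_error(site_recruitment_model("s", pw2, new_escape_curve(rep(0.5, 4))),
               class = "seedfate_validation_error")
})

test_that("pathway_contribution computes one summand of the recruitment equation", {
  e_unit <- new_escape_curve(c(1, 1, 1, 1))
  expect_equal(
    pathway_contribution(seed_fate_pathway("a", 1, 1, degenerate_kernel()),
                         e_unit), 100)
  # hand arithmetic: 100 * 0.5 * 0.8 * 0.25 = 10
  e <- new_escape_curve(c(0.25, 0.9, 0.9, 0.9))
  expect_equal(
    pathway_contribution(seed_fate_pathway("a", 0.5, 0.8, degenerate_kernel()),
                         e), 10)
  expect_equal(
    pathway_contribution(seed_fate_pathway("a", 0, 0.8, degenerate_kernel()),
                         e), 0)
  # kernel mass is aggregated by nearest experimental class before weighting:
  # bins [0,5) and [10,15) have midpoints 2.5 and 12.5 -> classes 1 and 2
  k <- distance_kernel(c(0.4, 0, 0.6))
  expect_equal(
    pathway_contribution(seed_fate_pathway("a", 1, 1, k),
                         new_escape_curve(c(0.1, 0.3, 0.7, 0.9))),
    100 * (0.4 * 0.1 + 0.6 * 0.3))
})

test_that("recruitment success is additive over pathways and bounded", {
  for (seed in 1:30) {
    m <- random_model(seed)
    r <- recruitment_success(m)
    expect_equal(r$rs_percent, sum(r$pathway_contributions), tolerance = 1e-12)
    expect_gte(r$rs_percent, 0)
    expect_lte(r$rs_percent, 100)
    expect_equal(sum(r$shares), 1, tolerance = 1e-9)
  }
  # two hand-computed summands: 10 + 5 = 15
  r <- recruitment_success(toy_15pct_model())
  expect_equal(r$rs_percent, 15)
  expect_equal(unname(r$pathway_contributions[c("a", "b")]), c(10, 5))
})

test_that("contribution shares normalise correctly and refuse zero recruitment", {
  r <- recruitment_success(toy_15pct_model())
  expect_equal(unname(contribution_shares(r)[c("a", "b")]), c(2 / 3, 1 / 3))
  single <- site_recruitment_model("s", list(
    seed_fate_pathway("only", 1, 0.5, degenerate_kernel())
  ), new_escape_curve(rep(0.5, 4)))
  expect_equal(unname(contribution_shares(recruitment_success(single))), 1)
  dead <- site_recruitment_model("s", list(
    seed_fate_pathway("a", 0.5, 0, degenerate_kernel()),
    seed_fate_pathway("undispersed", 0.5, 0, degenerate_kernel())
  ), new_escape_curve(rep(0.5, 4)))
  expect_error(contribution_shares(recruitment_success(dead)),
               class = "seedfate_undefined_shares")
})

test_that("recruitment success is monotone in survival, germination and quality", {
  for (seed in 31:45) {
    m <- random_model(seed)
    rs0 <- recruitment_success(m)$rs_percent
    # raise one survival class
    e2 <- m$escape
    e2$survival[2] <- min(1, e2$survival[2] + 0.1)
    expect_gte(recruitment_success(apply_predator_scenario(m, e2))$rs_percent,
               rs0)
    # raise one germination probability
    m2 <- m
    m2$pathways[[1]]$germination_prob <-
      min(1, m2$pathways[[1]]$germination_prob + 0.1)
    expect_gte(recruitment_success(m2)$rs_percent, rs0)
    # move removal mass from the lowest- to the highest-quality pathway
    qual <- vapply(m$pathways, function(pw) {
      pw$germination_prob *
        sum(seedfate:::kernel_class_mass(pw$kernel, m$escape) *
              m$escape$survival)
    }, numeric(1))
    lo <- which.min(qual); hi <- which.max(qual)
    shift <- m$pathways[[lo]]$removal_fraction / 2
    m3 <- m
    m3$pathways[[lo]]$removal_fraction <-
      m3$pathways[[lo]]$removal_fraction - shift
    m3$pathways[[hi]]$removal_fraction <-
      m3$pathways[[hi]]$removal_fraction + shift
    expect_gte(recruitment_success(m3)$rs_percent, rs0 - 1e-12)
  }
})

test_that("Monte-Carlo simulation agrees with the analytic result", {
  # degenerate cases are exact
  dead <- site_recruitment_model("s", list(
    seed_fate_pathway("a", 0.6, 0, degenerate_kernel()),
    seed_fate_pathway("undispersed", 0.4, 0, degenerate_kernel())
  ), new_escape_curve(rep(0.5, 4)))
  expect_equal(monte_carlo_rs(dead, 1000, rng_seed = 1)$rs_percent, 0)
  certain <- site_recruitment_model("s", list(
    seed_fate_pathway("a", 1, 1, degenerate_kernel())
  ), new_escape_curve(rep(1, 4)))
  expect_equal(monte_carlo_rs(certain, 1000, rng_seed = 1)$rs_percent, 100)
  # stochastic agreement on the 15% toy model
  mc <- monte_carlo_rs(toy_15pct_model(), 1e5, rng_seed = 42)
  expect_lt(abs(mc$rs_percent - 15), 3 * mc$se_percent)
  # reproducible under a fixed seed
  expect_identical(mc, monte_carlo_rs(toy_15pct_model(), 1e5, rng_seed = 42))
})

test_that("site models round-trip through YAML", {
  m <- random_model(77)
  path <- withr::local_tempfile(fileext = ".yaml")
  model_to_yaml(m, path)
  m2 <- model_from_yaml(path)
  expect_equal(removal_fractions(m2), removal_fractions(m), tolerance = 1e-12)
  expect_equal(m2$escape$survival, m$escape$survival, tolerance = 1e-12)
  for (lab in pathway_labels(m)) {
    expect_equal(m2$pathways[[lab]]$kernel$probs, m$pathways[[lab]]$kernel$probs,
                 tolerance = 1e-12)
  }
  expect_equal(recruitment_success(m2)$rs_percent,
               recruitment_success(m)$rs_percent, tolerance = 1e-10)
})
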