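#' Default ground truth for the synthetic-data generator
#'
#' A parameter set describing three Atlantic-Forest-like study sites along
#' a defaunation gradient of a large-seeded tree's seed dispersers
#' (muriqui, howler monkey, jacutinga) and seed predators:
#'
#' * `intact` — all three dispersers present (muriqui removes 41% of the
#'   crop, howler 41%, jacutinga 1%, 83% swallowed in total), but large
#'   seed predators depleted, so small-rodent release flattens the escape
#'   curve at a low survival level;
#' * `moderate` — no muriquis (howler 47%, jacutinga 16%, 63% swallowed),
#'   complete seed-predator community, clear escape curve (survival rises
#'   with distance);
#' * `defaunated` — jacutinga the only disperser (41% swallowed), most
#'   large predators present, intermediate escape curve.
#'
#' Dispersal kernels are log-normal with moments 59.7 +/- 35.7 m
#' (muriqui), 9.7 +/- 3.4 m (howler) and 10.5 +/- 7.3 m (jacutinga).
#' Germination is higher after primate gut passage than for seeds with or
#' without pulp, while jacutinga-defecated seeds germinate like pulp-free
#' controls. Escape curves are log-linear in distance: `T(d) = base_5m *
#' exp(slope * (d - 5))`.
#'
#' @return object of class `"synthetic_truth"`: `sites` (per-site fate
#'   profile, escape parameters and per-species visitation rates per 100
#'   trap-days), `germination` (per-treatment probabilities),
#'   `kernels` (per-disperser family and moments), `block_sd`
#'   (logit-scale SD of germination block effects).
#' @export
default_truth <- function() {
  profile <- function(site, swallowed, spat, undisp) {
    structure(list(site = site, swallowed_by = swallowed, spat_out = spat,
                   undispersed = undisp,
                   n_fruits = NA_integer_),
              class = "seed_fate_profile")
  }
  truth <- structure(list(
    sites = list(
      intact = list(
        profile = profile("intact",
                          c(muriqui = 0.41, howler = 0.41, jacutinga = 0.01),
                          spat = 0.10, undisp = 0.07),
        escape = list(base_5m = 0.08, slope = 0.001),
        visitation = c(small_rodent = 70, peccary = 0.5, agouti = 1)
      ),
      moderate = list(
        profile = profile("moderate",
                          c(howler = 0.47, jacutinga = 0.16),
                          spat = 0.15, undisp = 0.22),
        escape = list(base_5m = 0.20, slope = 0.015),
        visitation = c(small_rodent = 5, peccary = 8, agouti = 6)
      ),
      defaunated = list(
        profile = profile("defaunated",
                          c(jacutinga = 0.41),
                          spat = 0.20, undisp = 0.39),
        escape = list(base_5m = 0.15, slope = 0.012),
        visitation = c(small_rodent = 40, peccary = 1, agouti = 5)
      )
    ),
    germination = c(defecated_muriqui = 0.80, defecated_howler = 0.75,
                    defecated_jacutinga = 0.50, without_pulp = 0.48,
                    with_pulp = 0.40),
    kernels = list(
      muriqui = list(family = "lognormal", mean = 59.7, sd = 35.7),
      howler = list(family = "lognormal", mean = 9.7, sd = 3.4),
      jacutinga = list(family = "lognormal", mean = 10.5, sd = 7.3)
    ),
    block_sd = 0.5
  ), class = "synthetic_truth")
  validate_truth(truth)
  truth
}

validate_truth <- function(truth) {
  for (s in names(truth$sites)) {
    pr <- truth$sites[[s]]$profile
    total <- sum(pr$swallowed_by) + pr$spat_out + pr$undispersed
    if (abs(total - 1) > 1e-9) {
      stop_sf(sprintf("site '%s' fate profile sums to %.12f, not 1", s, total),
              "seedfate_validation_error")
    }
    assert_prob(c(pr$swallowed_by, pr$spat_out, pr$undispersed),
                sprintf("site '%s' fate fractions", s))
    esc <- truth$sites[[s]]$escape
    if (escape_truth_survival(esc, 50) > 1) {
      stop_sf(sprintf("site '%s' escape parameters imply survival > 1", s),
              "seedfate_validation_error")
    }
  }
  assert_prob(truth$germination, "germination probabilities")
  for (k in truth$kernels) stopifnot(k$sd >= 0, k$mean > 0)
  invisible(truth)
}

escape_truth_survival <- function(esc, distance_m) {
  esc$base_5m * exp(esc$slope * (distance_m - 5))
}

# log-normal / gamma parameterisation by method of moments
kernel_draw <- function(spec, n) {
  m <- spec$mean; s <- spec$sd
  if (s <= 0) return(rep(m, n))
  switch(spec$family,
    lognormal = {
      sigma2 <- log(1 + (s / m)^2)
      stats::rlnorm(n, meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
    },
    gamma = stats::rgamma(n, shape = (m / s)^2, rate = m / s^2),
    stop_sf(sprintf("unknown kernel family '%s'", spec$family),
            "seedfate_validation_error")
  )
}

# exact binned probabilities of a truth kernel on 5 m bins; the last bin
# absorbs the far tail so the kernel sums to one
kernel_truth_binned <- function(spec, bin_width = 5, max_m = 300) {
  m <- spec$mean; s <- spec$sd
  edges <- seq(0, max_m, by = bin_width)
  cdf <- if (s <= 0) {
    as.numeric(edges > m)
  } else if (spec$family == "lognormal") {
    sigma2 <- log(1 + (s / m)^2)
    stats::plnorm(edges, meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
  } else {
    stats::pgamma(edges, shape = (m / s)^2, rate = m / s^2)
  }
  probs <- diff(cdf)
  probs[length(probs)] <- probs[length(probs)] + (1 - cdf[length(cdf)])
  distance_kernel(probs / sum(probs), bin_width = bin_width)
}

#' Simulate focal fruit-handling observations
#'
#' Draws a multinomial seed fate (swallowed by each disperser, spat out,
#' dropped) for each fruit from the site's true fate profile and packages
#' the counts as per-tree, per-session focal records: one row per disperser
#' per session with its swallowed count, plus an actor `"none"` row
#' carrying the session's spat and dropped counts.
#'
#' @param truth a [default_truth()]-style object.
#' @param site site name in `truth$sites`.
#' @param n_fruits total number of handled fruits to simulate.
#' @param rng_seed integer seed.
#' @param n_trees number of focal trees (>= 3), each observed in two
#'   sessions.
#' @return data.frame of focal records (see [seed_fate_profile()]).
#' @export
simulate_focal_observations <- function(truth, site, n_fruits,
                                        rng_seed = NULL, n_trees = 4) {
  stopifnot(inherits(truth, "synthetic_truth"), n_fruits >= 1, n_trees >= 3)
  pr <- truth$sites[[site]]$profile
  if (is.null(pr)) {
    stop_sf(sprintf("unknown site '%s'", site), "seedfate_validation_error")
  }
  cats <- c(names(pr$swallowed_by), "spat_out", "undispersed")
  p <- c(pr$swallowed_by, pr$spat_out, pr$undispersed)
  with_seed(rng_seed, {
    n_sessions <- 2L * n_trees
    session_of <- sort(rep_len(seq_len(n_sessions), n_fruits))
    rows <- list()
    for (ses in seq_len(n_sessions)) {
      n_ses <- sum(session_of == ses)
      counts <- as.vector(stats::rmultinom(1, n_ses, prob = p))
      tree <- paste0("tree_", (ses - 1L) %/% 2L + 1L)
      hours <- round(n_ses / 25 + stats::runif(1, 0.5, 1.5), 1)
      for (i in seq_along(pr$swallowed_by)) {
        rows[[length(rows) + 1]] <- data.frame(
          site = site, tree_id = tree, session_hours = hours,
          actor = cats[i], n_swallowed = counts[i], n_spat = 0L,
          n_dropped = 0L, stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1]] <- data.frame(
        site = site, tree_id = tree, session_hours = hours, actor = "none",
        n_swallowed = 0L, n_spat = counts[length(counts) - 1L],
        n_dropped = counts[length(counts)], stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate randomized-block germination trials
#'
#' Each block draws a shared normal effect on the logit scale; within a
#' block, each treatment's germinated count is binomial with probability
#' `plogis(qlogis(p_treatment) + block_effect)`.
#'
#' @param truth a [default_truth()]-style object.
#' @param site site label stamped on the records.
#' @param treatments treatment labels (default all in
#'   `truth$germination`).
#' @param n_blocks replicate blocks (design value 10).
#' @param n_sown seeds per block (design value 5).
#' @param rng_seed integer seed.
#' @return data.frame of germination trials (see [germination_rate()]).
#' @export
simulate_germination_trials <- function(truth, site = "intact",
                                        treatments = NULL, n_blocks = 10,
                                        n_sown = 5, rng_seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"), n_blocks >= 1, n_sown >= 1)
  if (is.null(treatments)) treatments <- names(truth$germination)
  unknown <- setdiff(treatments, names(truth$germination))
  if (length(unknown)) {
    stop_sf(sprintf("unknown treatment(s): %s", paste(unknown, collapse = ", ")),
            "seedfate_validation_error")
  }
  with_seed(rng_seed, {
    block_eff <- stats::rnorm(n_blocks, 0, truth$block_sd)
    out <- expand.grid(block_id = paste0("block_", seq_len(n_blocks)),
                       treatment = treatments, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
    p_t <- truth$germination[out$treatment]
    p <- stats::plogis(stats::qlogis(p_t) +
                         block_eff[match(out$block_id,
                                         paste0("block_", seq_len(n_blocks)))])
    p[p_t == 0] <- 0; p[p_t == 1] <- 1
    out$site <- site
    out$n_sown <- n_sown
    out$n_germinated <- stats::rbinom(nrow(out), n_sown, p)
    out[, c("site", "treatment", "block_id", "n_sown", "n_germinated")]
  })
}

#' Simulate dispersal distances for one disperser
#'
#' @param truth a [default_truth()]-style object.
#' @param disperser disperser name in `truth$kernels`.
#' @param n number of dispersal events.
#' @param rng_seed integer seed.
#' @return a [distance_sample()].
#' @export
simulate_dispersal_distances <- function(truth, disperser, n,
                                         rng_seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"), n >= 1)
  spec <- truth$kernels[[disperser]]
  if (is.null(spec)) {
    stop_sf(sprintf("unknown disperser '%s'", disperser),
            "seedfate_validation_error")
  }
  with_seed(rng_seed, distance_sample(kernel_draw(spec, n), disperser))
}

#' Simulate a distance-dependent seed-survival experiment
#'
#' Seeds are placed at the four experimental distances under `n_trees`
#' trees; each station's one-year survivors are binomial with probability
#' `base_5m * exp(slope * (d - 5))`, the site's log-linear escape curve.
#'
#' @param truth a [default_truth()]-style object.
#' @param site site name in `truth$sites`.
#' @param n_per_distance total seeds per distance class (default 60, i.e.
#'   240 per site-year over the four classes).
#' @param n_trees trees the seeds are spread across.
#' @param year year stamped on the records.
#' @param rng_seed integer seed.
#' @param distances_m the experimental distances.
#' @return data.frame of survival records (see [escape_curve()]).
#' @export
simulate_survival_experiment <- function(truth, site, n_per_distance = 60,
                                         n_trees = 20, year = 2011,
                                         rng_seed = NULL,
                                         distances_m = c(5, 15, 30, 50)) {
  stopifnot(inherits(truth, "synthetic_truth"), n_per_distance >= 1,
            n_trees >= 1)
  esc <- truth$sites[[site]]$escape
  if (is.null(esc)) {
    stop_sf(sprintf("unknown site '%s'", site), "seedfate_validation_error")
  }
  p_d <- escape_truth_survival(esc, distances_m)
  if (any(p_d > 1)) {
    stop_sf("escape parameters imply survival > 1 within the design range",
            "seedfate_validation_error")
  }
  per_tree <- diff(round(seq(0, n_per_distance, length.out = n_trees + 1)))
  with_seed(rng_seed, {
    out <- expand.grid(tree_id = paste0("tree_", seq_len(n_trees)),
                       distance_m = distances_m, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
    out$site <- site
    out$year <- year
    out$n_placed <- per_tree[match(out$tree_id,
                                   paste0("tree_", seq_len(n_trees)))]
    out$n_surviving <- stats::rbinom(nrow(out), out$n_placed,
                                     p_d[match(out$distance_m, distances_m)])
    out <- out[out$n_placed > 0, ]
    rownames(out) <- NULL
    out[, c("site", "year", "tree_id", "distance_m", "n_placed",
            "n_surviving")]
  })
}

#' Simulate camera-trap visitation records
#'
#' Visits per station and species are Poisson with mean `rate *
#' trap_days / 100`, the site's true visitation rate per 100 trap-days.
#'
#' @param truth a [default_truth()]-style object.
#' @param site site name in `truth$sites`.
#' @param trap_days total camera effort in days, split over stations.
#' @param rng_seed integer seed.
#' @param n_stations number of camera stations.
#' @return data.frame of camera records (see [visitation_rate()]).
#' @export
simulate_camera_traps <- function(truth, site, trap_days, rng_seed = NULL,
                                  n_stations = 5) {
  stopifnot(inherits(truth, "synthetic_truth"), trap_days > 0,
            n_stations >= 1)
  rates <- truth$sites[[site]]$visitation
  if (is.null(rates)) {
    stop_sf(sprintf("unknown site '%s'", site), "seedfate_validation_error")
  }
  days <- diff(round(seq(0, trap_days, length.out = n_stations + 1)))
  days[days <= 0] <- 1
  with_seed(rng_seed, {
    out <- expand.grid(station_id = paste0("cam_", seq_len(n_stations)),
                       species = names(rates), stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
    out$site <- site
    out$trap_days <- days[match(out$station_id,
                                paste0("cam_", seq_len(n_stations)))]
    out$n_visits <- stats::rpois(nrow(out),
                                 rates[out$species] * out$trap_days / 100)
    out[, c("site", "station_id", "trap_days", "species", "n_visits")]
  })
}

#' Analytic site model implied by a synthetic truth
#'
#' Builds the exact [site_recruitment_model()] a perfect estimator would
#' recover: true fate fractions, true germination probabilities, exactly
#' binned true kernels, and the true escape curve evaluated at the
#' experimental distances. The recruitment success of this model is the
#' ground truth against which pipeline recovery is judged.
#'
#' @param truth a [default_truth()]-style object.
#' @param site site name in `truth$sites`.
#' @param bin_width kernel bin width in metres.
#' @param distances_m experimental distances of the escape curve.
#' @return a [site_recruitment_model()].
#' @export
truth_model <- function(truth, site, bin_width = 5,
                        distances_m = c(5, 15, 30, 50)) {
  stopifnot(inherits(truth, "synthetic_truth"))
  site_def <- truth$sites[[site]]
  if (is.null(site_def)) {
    stop_sf(sprintf("unknown site '%s'", site), "seedfate_validation_error")
  }
  pr <- site_def$profile
  pathways <- lapply(names(pr$swallowed_by), function(d) {
    seed_fate_pathway(d, pr$swallowed_by[[d]],
                      truth$germination[[paste0("defecated_", d)]],
                      kernel_truth_binned(truth$kernels[[d]], bin_width))
  })
  pathways <- c(pathways, list(
    seed_fate_pathway("spat_out", pr$spat_out,
                      truth$germination[["without_pulp"]],
                      degenerate_kernel(bin_width)),
    seed_fate_pathway("undispersed", pr$undispersed,
                      truth$germination[["with_pulp"]],
                      degenerate_kernel(bin_width))
  ))
  esc <- new_escape_curve(escape_truth_survival(site_def$escape, distances_m),
                          distances_m = distances_m, site = site)
  site_recruitment_model(site, pathways, esc)
}

#' Write a complete synthetic dataset to disk
#'
#' Generates all five record tables for every site in the truth (focal
#' observations, germination trials, dispersal distances, survival
#' experiments over two years, camera traps) plus a `truth.yaml` with the
#' generating parameters, using deterministic per-table child seeds derived
#' from `rng_seed`.
#'
#' @param truth a [default_truth()]-style object.
#' @param dir output directory (created if needed).
#' @param n_fruits handled fruits per site.
#' @param n_distances dispersal events per disperser.
#' @param n_per_distance seeds per survival distance class per site-year.
#' @param trap_days camera effort per site.
#' @param n_blocks germination blocks per treatment.
#' @param rng_seed master integer seed.
#' @return invisibly, a named vector of the file paths written.
#' @export
write_synthetic_dataset <- function(truth, dir, n_fruits = 2000,
                                    n_distances = 500, n_per_distance = 60,
                                    trap_days = 400, n_blocks = 10,
                                    rng_seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sites <- names(truth$sites)
  focal <- do.call(rbind, lapply(seq_along(sites), function(i) {
    simulate_focal_observations(truth, sites[i], n_fruits,
                                rng_seed = child_seed(rng_seed, i))
  }))
  germ <- do.call(rbind, lapply(seq_along(sites), function(i) {
    simulate_germination_trials(truth, sites[i], n_blocks = n_blocks,
                                rng_seed = child_seed(rng_seed, 10 + i))
  }))
  disp <- names(truth$kernels)
  dist <- do.call(rbind, lapply(seq_along(disp), function(i) {
    s <- simulate_dispersal_distances(truth, disp[i], n_distances,
                                      rng_seed = child_seed(rng_seed, 20 + i))
    data.frame(disperser = disp[i], distance_m = s$distances_m,
               stringsAsFactors = FALSE)
  }))
  surv <- do.call(rbind, lapply(seq_along(sites), function(i) {
    rbind(
      simulate_survival_experiment(truth, sites[i], n_per_distance,
                                   year = 2011,
                                   rng_seed = child_seed(rng_seed, 30 + i)),
      simulate_survival_experiment(truth, sites[i], n_per_distance,
                                   year = 2012,
                                   rng_seed = child_seed(rng_seed, 40 + i))
    )
  }))
  cams <- do.call(rbind, lapply(seq_along(sites), function(i) {
    simulate_camera_traps(truth, sites[i], trap_days,
                          rng_seed = child_seed(rng_seed, 50 + i))
  }))
  paths <- c(
    focal = file.path(dir, "focal_records.csv"),
    germination = file.path(dir, "germination_trials.csv"),
    distances = file.path(dir, "dispersal_distances.csv"),
    survival = file.path(dir, "survival_records.csv"),
    cameras = file.path(dir, "camera_records.csv"),
    truth = file.path(dir, "truth.yaml")
  )
  utils::write.csv(focal, paths[["focal"]], row.names = FALSE)
  utils::write.csv(germ, paths[["germination"]], row.names = FALSE)
  utils::write.csv(dist, paths[["distances"]], row.names = FALSE)
  utils::write.csv(surv, paths[["survival"]], row.names = FALSE)
  utils::write.csv(cams, paths[["cameras"]], row.names = FALSE)
  truth_plain <- unclass(truth)
  truth_plain$sites <- lapply(truth$sites, function(s) {
    s$profile <- unclass(s$profile)
    s$visitation <- as.list(s$visitation)
    s
  })
  truth_plain$germination <- as.list(truth$germination)
  yaml::write_yaml(truth_plain, paths[["truth"]], precision = 15)
  invisible(paths)
}
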