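#' Seed-fate profile of a site from focal-observation records
#'
#' Pools fruit-handling counts across trees and sessions (effort-weighted,
#' not tree-averaged: the recruitment model needs crop-level probabilities)
#' and converts them to the site's seed-fate fractions: the fraction
#' swallowed by each disperser, the fraction spat out, and the undispersed
#' fraction (dropped fruits fall under the crown with pulp and are merged
#' into "undispersed").
#'
#' @param records data.frame of focal records with columns `site`,
#'   `tree_id`, `session_hours`, `actor`, `n_swallowed`, `n_spat`,
#'   `n_dropped`.
#' @param site site identifier to select.
#' @return object of class `"seed_fate_profile"`: `site`, `swallowed_by`
#'   (named fractions per disperser), `spat_out`, `undispersed`,
#'   `n_fruits` (total fruits pooled). Fractions sum to 1.
#' @export
seed_fate_profile <- function(records, site) {
  assert_cols(records, c("site", "tree_id", "session_hours", "actor",
                         "n_swallowed", "n_spat", "n_dropped"),
              "focal records")
  rec <- records[records$site == site, , drop = FALSE]
  bad <- which(rec$actor == "none" & rec$n_swallowed > 0)
  if (length(bad)) {
    stop_sf(sprintf("focal record row(s) %s: actor 'none' cannot swallow fruits",
                    paste(bad, collapse = ", ")), "seedfate_schema_error")
  }
  if (any(rec$n_swallowed < 0 | rec$n_spat < 0 | rec$n_dropped < 0)) {
    stop_sf("focal counts must be non-negative", "seedfate_schema_error")
  }
  total <- sum(rec$n_swallowed) + sum(rec$n_spat) + sum(rec$n_dropped)
  if (nrow(rec) == 0 || total == 0) {
    stop_sf(sprintf("no handled fruits recorded at site '%s'", site),
            "seedfate_empty_data")
  }
  sw <- rec[rec$actor != "none" & rec$n_swallowed > 0, , drop = FALSE]
  swallowed_by <- if (nrow(sw)) {
    tapply(sw$n_swallowed, sw$actor, sum) / total
  } else {
    numeric(0)
  }
  structure(
    list(site = site,
         swallowed_by = stats::setNames(as.numeric(swallowed_by),
                                        names(swallowed_by)),
         spat_out = sum(rec$n_spat) / total,
         undispersed = sum(rec$n_dropped) / total,
         n_fruits = total),
    class = "seed_fate_profile"
  )
}

#' @export
print.seed_fate_profile <- function(x, ...) {
  cat(sprintf("seed_fate_profile [site %s], %d fruits\n", x$site, x$n_fruits))
  print(round(c(x$swallowed_by, spat_out = x$spat_out,
                undispersed = x$undispersed), 4))
  invisible(x)
}

#' Seed-removal probability of one disperser
#'
#' @param profile a [seed_fate_profile()].
#' @param disperser disperser name; a disperser absent from the profile has
#'   removal probability 0.
#' @return `P_s` in `[0, 1]`.
#' @export
removal_probability <- function(profile, disperser) {
  stopifnot(inherits(profile, "seed_fate_profile"))
  p <- profile$swallowed_by[disperser]
  if (is.na(p)) 0 else as.numeric(p)
}

#' Germination probability of a seed treatment
#'
#' Pools germinated counts over blocks for one treatment and reports the
#' pooled germination probability plus the per-block mean and standard
#' deviation of germinated counts (the convention of germination-trial bar
#' plots: mean germinated out of `n_sown`, with SD across replicates).
#'
#' @param trials data.frame of germination trials with columns `site`,
#'   `treatment`, `block_id`, `n_sown`, `n_germinated`.
#' @param treatment treatment label, e.g. `"defecated_muriqui"`,
#'   `"with_pulp"`, `"without_pulp"`.
#' @return list with `rate` (pooled `G`), `mean_per_block`, `sd_per_block`,
#'   `n_blocks`, `n_sown_total`.
#' @export
germination_rate <- function(trials, treatment) {
  assert_cols(trials, c("site", "treatment", "block_id", "n_sown",
                        "n_germinated"), "germination trials")
  if (any(trials$n_germinated < 0 | trials$n_germinated > trials$n_sown)) {
    stop_sf("n_germinated must lie in [0, n_sown]", "seedfate_schema_error")
  }
  tr <- trials[trials$treatment == treatment, , drop = FALSE]
  if (!nrow(tr)) {
    stop_sf(sprintf("unknown treatment '%s'; known treatments: %s",
                    treatment,
                    paste(sort(unique(trials$treatment)), collapse = ", ")),
            "seedfate_unknown_treatment")
  }
  list(rate = sum(tr$n_germinated) / sum(tr$n_sown),
       mean_per_block = mean(tr$n_germinated),
       sd_per_block = stats::sd(tr$n_germinated),
       n_blocks = nrow(tr),
       n_sown_total = sum(tr$n_sown))
}

#' One-way ANOVA for a randomized complete block design
#'
#' Partitions the total sum of squares of per-block germinated counts into
#' treatment, block and residual components and tests the treatment effect
#' with `F = MS_treatment / MS_residual` on `(t - 1, (t - 1)(b - 1))`
#' degrees of freedom. The layout must be complete and balanced: exactly
#' one observation per treatment x block cell; anything else is a design
#' error, never silently dropped. Counts are treated as continuous, the
#' standard design-based analysis of such trials.
#'
#' @param trials data.frame of germination trials (see
#'   [germination_rate()]).
#' @param treatments treatment labels to compare; default all present.
#' @return object of class `"anova_result"`: `f_statistic`,
#'   `df_treatment`, `df_error`, `p_value`, `treatment_means`, plus the
#'   sums of squares `ss_treatment`, `ss_block`, `ss_residual`.
#' @export
randomized_block_anova <- function(trials, treatments = NULL) {
  assert_cols(trials, c("treatment", "block_id", "n_germinated"),
              "germination trials")
  if (is.null(treatments)) treatments <- sort(unique(trials$treatment))
  tr <- trials[trials$treatment %in% treatments, , drop = FALSE]
  blocks <- sort(unique(tr$block_id))
  t_n <- length(treatments); b_n <- length(blocks)
  if (t_n < 2 || b_n < 2) {
    stop_sf("need at least 2 treatments and 2 blocks", "seedfate_design_error")
  }
  cell_n <- table(factor(tr$treatment, levels = treatments),
                  factor(tr$block_id, levels = blocks))
  if (any(cell_n != 1)) {
    off <- which(cell_n != 1, arr.ind = TRUE)[1, ]
    stop_sf(sprintf(
      "incomplete or unbalanced block design: treatment '%s' x block '%s' has %d observations (need exactly 1)",
      treatments[off[1]], blocks[off[2]],
      cell_n[off[1], off[2]]), "seedfate_design_error")
  }
  y <- matrix(NA_real_, t_n, b_n, dimnames = list(treatments, blocks))
  y[cbind(match(tr$treatment, treatments), match(tr$block_id, blocks))] <-
    tr$n_germinated
  grand <- mean(y)
  ss_total <- sum((y - grand)^2)
  trt_means <- rowMeans(y)
  blk_means <- colMeans(y)
  ss_trt <- b_n * sum((trt_means - grand)^2)
  ss_blk <- t_n * sum((blk_means - grand)^2)
  ss_res <- ss_total - ss_trt - ss_blk
  df_trt <- t_n - 1L
  df_err <- (t_n - 1L) * (b_n - 1L)
  ms_trt <- ss_trt / df_trt
  ms_res <- ss_res / df_err
  tol <- 1e-12 * max(1, ss_total)
  if (ms_trt <= tol) {
    f <- 0; p <- 1
  } else if (ms_res <= tol) {
    f <- Inf; p <- 0
  } else {
    f <- ms_trt / ms_res
    p <- stats::pf(f, df_trt, df_err, lower.tail = FALSE)
  }
  structure(
    list(f_statistic = f, df_treatment = df_trt, df_error = df_err,
         p_value = p, treatment_means = trt_means,
         ss_treatment = ss_trt, ss_block = ss_blk, ss_residual = ss_res),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("randomized-block ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df_treatment, x$df_error, x$f_statistic, x$p_value))
  invisible(x)
}

#' Camera-trap visitation rate
#'
#' Raw relative visitation frequency of a species group at a site, in
#' visits per 100 trap-days. Effort is counted once per camera station
#' (records are one row per station x species, all sharing the station's
#' `trap_days`).
#'
#' @param records data.frame of camera records with columns `site`,
#'   `station_id`, `trap_days`, `species`, `n_visits`.
#' @param species_group character vector of species names to pool.
#' @param site site identifier.
#' @return visits per 100 trap-days.
#' @export
visitation_rate <- function(records, species_group, site) {
  assert_cols(records, c("site", "station_id", "trap_days", "species",
                         "n_visits"), "camera records")
  rec <- records[records$site == site, , drop = FALSE]
  if (any(rec$trap_days <= 0)) {
    stop_sf("trap_days must be positive", "seedfate_schema_error")
  }
  effort <- sum(rec$trap_days[!duplicated(rec$station_id)])
  if (!nrow(rec) || effort <= 0) {
    stop_sf(sprintf("no camera-trap effort recorded at site '%s'", site),
            "seedfate_empty_data")
  }
  visits <- sum(rec$n_visits[rec$species %in% species_group])
  100 * visits / effort
}
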