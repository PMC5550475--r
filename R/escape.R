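#' Estimate an escape curve from seed-survival records
#'
#' Pools surviving and placed counts per experimental distance class for a
#' site (and optionally a subset of years) and returns the design-based
#' survival estimates `T_m = surviving / placed`. A distance class with no
#' data is an error, never an imputation; the estimates are invariant to
#' how the records are split across trees.
#'
#' @param records data.frame of survival records with columns `site`,
#'   `year`, `tree_id`, `distance_m`, `n_placed`, `n_surviving`.
#' @param site site identifier.
#' @param years `"pooled"` (default) to pool all years, or an integer
#'   vector of years to keep.
#' @param distances_m the experimental distance classes.
#' @return an `"escape_curve"` (see [new_escape_curve()]).
#' @export
escape_curve <- function(records, site, years = "pooled",
                         distances_m = c(5, 15, 30, 50)) {
  assert_cols(records, c("site", "year", "tree_id", "distance_m",
                         "n_placed", "n_surviving"), "survival records")
  if (any(records$n_surviving < 0 | records$n_surviving > records$n_placed)) {
    stop_sf("n_surviving must lie in [0, n_placed]", "seedfate_schema_error")
  }
  rec <- records[records$site == site, , drop = FALSE]
  keep_years <- if (identical(years, "pooled")) sort(unique(rec$year)) else years
  rec <- rec[rec$year %in% keep_years, , drop = FALSE]
  bad_d <- setdiff(unique(rec$distance_m), distances_m)
  if (length(bad_d)) {
    stop_sf(sprintf("distance(s) %s m are not in the experimental design (%s m)",
                    paste(bad_d, collapse = ", "),
                    paste(distances_m, collapse = ", ")),
            "seedfate_schema_error")
  }
  survival <- vapply(distances_m, function(d) {
    at <- rec[rec$distance_m == d, , drop = FALSE]
    placed <- sum(at$n_placed)
    if (!nrow(at) || placed == 0) {
      stop_sf(sprintf(
        "no seeds placed at the %g m class for site '%s' (years %s)",
        d, site, paste(keep_years, collapse = "/")),
        "seedfate_missing_class")
    }
    sum(at$n_surviving) / placed
  }, numeric(1))
  new_escape_curve(survival, distances_m = distances_m, site = site,
                   years = as.integer(keep_years))
}

#' Test the distance trend in seed survival
#'
#' Fixed-effects log-link count regression of surviving seeds on distance
#' to the parent tree, with a `log(n_placed)` offset and tree-indicator
#' adjustments where more than one tree is present. The slope is the
#' log-scale change in survival per metre; the Wald z statistic tests the
#' escape (Janzen-Connell) prediction that survival increases with
#' distance.
#'
#' @param records data.frame of survival records (see [escape_curve()]).
#' @param site site identifier.
#' @param year single year, or `"pooled"` (default) to use all years.
#' @return object of class `"trend_test_result"`: `slope` (per metre,
#'   log scale), `se`, `z_statistic`, `p_value` (two-sided), `n` (records
#'   used).
#' @export
distance_trend_test <- function(records, site, year = "pooled") {
  assert_cols(records, c("site", "year", "tree_id", "distance_m",
                         "n_placed", "n_surviving"), "survival records")
  rec <- records[records$site == site, , drop = FALSE]
  if (!identical(year, "pooled")) rec <- rec[rec$year %in% year, , drop = FALSE]
  rec <- rec[rec$n_placed > 0, , drop = FALSE]
  if (length(unique(rec$distance_m)) < 2) {
    stop_sf("need data at >= 2 distance classes", "seedfate_design_error")
  }
  if (all(rec$n_surviving == 0)) {
    stop_sf("degenerate fit: no seed survived at any distance",
            "seedfate_degenerate_fit")
  }
  rec$tree_id <- factor(rec$tree_id)
  fit <- if (nlevels(rec$tree_id) > 1) {
    stats::glm(n_surviving ~ distance_m + tree_id,
               family = stats::poisson(link = "log"),
               offset = log(n_placed), data = rec)
  } else {
    stats::glm(n_surviving ~ distance_m,
               family = stats::poisson(link = "log"),
               offset = log(n_placed), data = rec)
  }
  co <- summary(fit)$coefficients["distance_m", ]
  structure(
    list(slope = unname(co["Estimate"]), se = unname(co["Std. Error"]),
         z_statistic = unname(co["z value"]),
         p_value = unname(co["Pr(>|z|)"]), n = nrow(rec)),
    class = "trend_test_result"
  )
}

#' @export
print.trend_test_result <- function(x, ...) {
  cat(sprintf(
    "distance trend in survival: slope = %.4f /m (log scale), z = %.2f, p = %.4g, n = %d\n",
    x$slope, x$z_statistic, x$p_value, x$n))
  invisible(x)
}
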