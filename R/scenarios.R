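#' Remove a disperser from a site model
#'
#' Simulates the local extinction of a seed disperser. Without
#' compensation, the removed pathway's removal fraction is reallocated to
#' the "undispersed" pathway (its fruits fall with pulp under the crown)
#' and every other pathway is untouched. With compensation, all removal
#' fractions are rewired to those of a profile observed in a community that
#' already lacks the removed disperser; germination probabilities and
#' kernels of the remaining pathways keep their original values, since only
#' seed removal is observed to shift.
#'
#' @param model a [site_recruitment_model()].
#' @param disperser name of the disperser to remove; removing a disperser
#'   absent from the model is a no-op.
#' @param compensation_profile `"none"` (default) or a
#'   [seed_fate_profile()] observed without the removed disperser.
#' @return a new, validated [site_recruitment_model()].
#' @export
remove_disperser <- function(model, disperser, compensation_profile = "none") {
  stopifnot(inherits(model, "site_recruitment_model"))
  if (!disperser %in% pathway_labels(model)) return(model)
  if (!"undispersed" %in% pathway_labels(model)) {
    stop_sf("model has no 'undispersed' pathway to absorb the removed mass",
            "seedfate_validation_error")
  }
  pw <- model$pathways
  if (identical(compensation_profile, "none")) {
    freed <- pw[[disperser]]$removal_fraction
    pw[[disperser]]$removal_fraction <- 0
    pw[["undispersed"]]$removal_fraction <-
      pw[["undispersed"]]$removal_fraction + freed
    return(site_recruitment_model(model$site, pw, model$escape))
  }
  stopifnot(inherits(compensation_profile, "seed_fate_profile"))
  if (disperser %in% names(compensation_profile$swallowed_by)) {
    stop_sf(sprintf(
      "compensation profile still contains the removed disperser '%s'",
      disperser), "seedfate_compensation_error")
  }
  apply_compensation(model, compensation_profile)
}

# rewire all removal fractions of `model` to those of `profile`; dispersers
# absent from the profile must already have zero removal in the model
apply_compensation <- function(model, profile) {
  stopifnot(inherits(model, "site_recruitment_model"),
            inherits(profile, "seed_fate_profile"))
  pw <- model$pathways
  labels <- names(pw)
  missing <- setdiff(names(profile$swallowed_by), dispersers(model))
  if (length(missing)) {
    stop_sf(sprintf(
      "compensation profile names disperser(s) absent from the model: %s",
      paste(missing, collapse = ", ")), "seedfate_compensation_error")
  }
  for (lab in labels) {
    pw[[lab]]$removal_fraction <- switch(
      lab,
      spat_out = profile$spat_out,
      undispersed = profile$undispersed,
      {
        p <- profile$swallowed_by[lab]
        if (is.na(p)) 0 else as.numeric(p)
      }
    )
  }
  site_recruitment_model(model$site, pw, model$escape)
}

#' Substitute a site model's escape curve
#'
#' Implements a seed-predator scenario: the dispersal side of the model
#' (pathways) is kept and only the survival-by-distance curve is replaced,
#' e.g. by the curve measured at a site with a different predator
#' community.
#'
#' @param model a [site_recruitment_model()].
#' @param curve an `"escape_curve"`.
#' @return the model with `curve` as its escape curve.
#' @export
apply_predator_scenario <- function(model, curve) {
  stopifnot(inherits(model, "site_recruitment_model"),
            inherits(curve, "escape_curve"))
  site_recruitment_model(model$site, model$pathways, curve)
}

#' Relative change in recruitment success
#'
#' @param rs recruitment success, percent.
#' @param rs_reference reference recruitment success, percent; must be
#'   positive.
#' @return signed percent change `100 * (rs - rs_reference) /
#'   rs_reference`.
#' @export
#' @examples
#' relative_change(4.5, 9)  # -50
relative_change <- function(rs, rs_reference) {
  if (any(rs_reference <= 0)) {
    stop_sf("reference recruitment success must be positive",
            "seedfate_validation_error")
  }
  100 * (rs - rs_reference) / rs_reference
}

#' Disperser-loss x predator-scenario grid of recruitment success
#'
#' Enumerates cumulative disperser losses (in the given order, typically
#' largest to smallest body size) crossed with seed-predator scenarios
#' (escape-curve substitutions) and, where an observed source profile
#' exists, with compensatory rewiring of seed removal. Every cell's
#' recruitment success is computed by [recruitment_success()] on the cell's
#' fully constructed model; no shortcut arithmetic is used. Two relative
#' changes are reported per cell: against the full-assemblage baseline of
#' the reference predator scenario, and against the cell's own predator
#' scenario's full-assemblage baseline.
#'
#' @param base intact-community [site_recruitment_model()].
#' @param loss_order character vector of dispersers, removed cumulatively
#'   from first to last.
#' @param predator_curves named list of `"escape_curve"` objects, one per
#'   predator scenario; the first is the reference scenario unless
#'   `reference_scenario` says otherwise.
#' @param compensation_profiles named list of [seed_fate_profile()]
#'   objects keyed by the remaining-disperser set, sorted names joined with
#'   `"+"` (e.g. `"howler+jacutinga"`). Cells whose remaining set has no
#'   profile fall back to the uncompensated model, flagged in the output.
#' @param reference_scenario name of the predator scenario used as the
#'   global reference (default the first in `predator_curves`).
#' @return object of class `"scenario_grid"`: a data.frame with one row
#'   per cell and columns `predator_scenario`, `dispersers_present`,
#'   `n_lost`, `compensation`, `compensation_available`, `rs_percent`,
#'   `delta_vs_reference_percent` (vs the reference scenario's
#'   full-assemblage baseline) and `delta_vs_scenario_baseline_percent`.
#' @export
scenario_grid <- function(base, loss_order, predator_curves,
                          compensation_profiles = list(),
                          reference_scenario = names(predator_curves)[1]) {
  stopifnot(inherits(base, "site_recruitment_model"),
            is.list(predator_curves), length(predator_curves) >= 1,
            !is.null(names(predator_curves)))
  unknown <- setdiff(loss_order, dispersers(base))
  if (length(unknown)) {
    stop_sf(sprintf("loss_order names unknown disperser(s): %s",
                    paste(unknown, collapse = ", ")),
            "seedfate_validation_error")
  }
  if (!reference_scenario %in% names(predator_curves)) {
    stop_sf("reference_scenario must name one of predator_curves",
            "seedfate_validation_error")
  }
  set_key <- function(x) paste(sort(x), collapse = "+")

  # dispersal-side models per cumulative loss step, for both compensation
  # states; each step removes one more disperser from the previous
  # uncompensated model (removal commutes, so the order within a step set
  # does not matter)
  steps <- list()
  uncomp <- base
  for (k in 0:length(loss_order)) {
    if (k > 0) uncomp <- remove_disperser(uncomp, loss_order[k])
    remaining <- setdiff(dispersers(base), loss_order[seq_len(k)])
    comp_key <- set_key(remaining)
    has_comp <- k > 0 && comp_key %in% names(compensation_profiles)
    comp <- if (has_comp) {
      apply_compensation(uncomp, compensation_profiles[[comp_key]])
    } else {
      NULL
    }
    steps[[k + 1]] <- list(
      n_lost = k, remaining = remaining,
      label = if (length(remaining)) set_key(remaining) else "none",
      uncompensated = uncomp, compensated = comp, has_comp = has_comp)
  }

  rows <- list()
  baselines <- numeric(0)
  for (scen in names(predator_curves)) {
    baseline_model <- apply_predator_scenario(base, predator_curves[[scen]])
    baselines[scen] <- recruitment_success(baseline_model)$rs_percent
  }
  ref_rs <- baselines[[reference_scenario]]
  for (scen in names(predator_curves)) {
    curve <- predator_curves[[scen]]
    for (st in steps) {
      states <- list(list(compensation = FALSE, model = st$uncompensated,
                          available = TRUE))
      if (st$n_lost > 0) {
        states <- c(states, list(list(
          compensation = TRUE,
          model = if (st$has_comp) st$compensated else st$uncompensated,
          available = st$has_comp)))
      }
      for (state in states) {
        cell <- apply_predator_scenario(state$model, curve)
        rs <- recruitment_success(cell)$rs_percent
        rows[[length(rows) + 1]] <- data.frame(
          predator_scenario = scen,
          dispersers_present = st$label,
          n_lost = st$n_lost,
          compensation = state$compensation,
          compensation_available = state$available,
          rs_percent = rs,
          delta_vs_reference_percent = relative_change(rs, ref_rs),
          delta_vs_scenario_baseline_percent =
            relative_change(rs, baselines[[scen]]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference_scenario") <- reference_scenario
  attr(out, "baselines") <- baselines
  class(out) <- c("scenario_grid", "data.frame")
  out
}

#' Write a scenario grid to delimited text and JSON
#'
#' @param grid a `"scenario_grid"`.
#' @param dir output directory (created if needed).
#' @param basename file stem (default `"scenario_grid"`).
#' @return invisibly, the paths written.
#' @export
write_scenario_grid <- function(grid, dir, basename = "scenario_grid") {
  stopifnot(inherits(grid, "scenario_grid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(basename, ".csv"))
  json <- file.path(dir, paste0(basename, ".json"))
  utils::write.csv(as.data.frame(grid), csv, row.names = FALSE)
  jsonlite::write_json(as.data.frame(grid), json, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(c(csv = csv, json = json))
}

#' Plot a scenario grid
#'
#' Bubble plot of recruitment success over disperser-loss steps (x axis)
#' and predator scenarios (y axis); filled circles show compensated cells,
#' open circles uncompensated ones, with circle area proportional to
#' recruitment success.
#'
#' @param x a `"scenario_grid"`.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.scenario_grid <- function(x, ...) {
  scen <- unique(x$predator_scenario)
  steps <- unique(x[, c("n_lost", "dispersers_present")])
  steps <- steps[order(steps$n_lost), , drop = FALSE]
  xi <- match(x$n_lost, steps$n_lost)
  yi <- match(x$predator_scenario, scen)
  cex <- 0.4 + 3 * sqrt(x$rs_percent / max(x$rs_percent, 1e-12))
  graphics::plot(NA, xlim = c(0.5, nrow(steps) + 0.5),
                 ylim = c(0.5, length(scen) + 0.5), xaxt = "n", yaxt = "n",
                 xlab = "seed dispersers remaining",
                 ylab = "seed predator scenario", ...)
  graphics::axis(1, at = seq_len(nrow(steps)),
                 labels = steps$dispersers_present, las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_along(scen), labels = scen, las = 1,
                 cex.axis = 0.7)
  off <- ifelse(x$compensation, 0.15, -0.15)
  graphics::points(xi + off, yi, cex = cex,
                   pch = ifelse(x$compensation, 19, 21),
                   col = "grey30", bg = "white")
  invisible(x)
}
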