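#' Default pipeline configuration
#'
#' Builds the configuration list consumed by [run_estimation()] and
#' [run_scenarios()] for the three-site defaunation-gradient design of
#' [default_truth()]: site disperser lists, the largest-to-smallest loss
#' order, the predator-scenario to escape-curve-site mapping, and the
#' compensation-source mapping (each loss step borrows the seed-removal
#' profile observed at the real community already lacking those
#' dispersers).
#'
#' @param paths named character vector or list with elements `focal`,
#'   `germination`, `distances`, `survival`, `cameras` (file paths), e.g.
#'   the return value of [write_synthetic_dataset()].
#' @param years `"pooled"` or integer vector of years for escape curves.
#' @return a configuration list.
#' @export
default_config <- function(paths, years = "pooled") {
  list(
    paths = as.list(paths),
    sites = list(
      intact = list(dispersers = c("muriqui", "howler", "jacutinga")),
      moderate = list(dispersers = c("howler", "jacutinga")),
      defaunated = list(dispersers = "jacutinga")
    ),
    years = years,
    bin_width = 5,
    boundaries = c(10, 22.5, 40),
    distances_m = c(5, 15, 30, 50),
    scenario = list(
      base_site = "intact",
      loss_order = c("muriqui", "howler", "jacutinga"),
      predator_curves = list(complete = "moderate",
                             no_peccaries = "defaunated",
                             no_peccaries_no_agoutis = "intact"),
      compensation_sources = list("howler+jacutinga" = "moderate",
                                  "jacutinga" = "defaunated"),
      reference_scenario = "complete"
    )
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [default_config()].
#' @return a configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (field in c("paths", "sites", "scenario")) {
    if (is.null(cfg[[field]])) {
      stop_sf(sprintf("pipeline config is missing the '%s' field", field),
              "seedfate_config_error")
    }
  }
  cfg$years <- cfg$years %||% "pooled"
  cfg$bin_width <- cfg$bin_width %||% 5
  cfg$boundaries <- as.numeric(cfg$boundaries %||% c(10, 22.5, 40))
  cfg$distances_m <- as.numeric(cfg$distances_m %||% c(5, 15, 30, 50))
  cfg
}

#' Estimate per-site recruitment models from record tables
#'
#' Runs the full estimation stage: reads the five record tables, estimates
#' each site's seed-fate profile, each disperser's binned dispersal kernel
#' and germination probability, the two non-dispersed germination controls
#' (spat-out seeds use the pulp-free control, undispersed seeds the
#' with-pulp control), and each site's escape curve, then assembles one
#' validated [site_recruitment_model()] per configured site.
#'
#' @param config configuration list (see [default_config()]).
#' @param quiet suppress stage-level progress messages.
#' @return object of class `"estimation_result"`: `models` (named list of
#'   site models), `profiles`, `kernels`, `kernel_samples`, `germination`
#'   (per-treatment rates), `curves`.
#' @export
run_estimation <- function(config, quiet = FALSE) {
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  p <- config$paths
  focal <- read_focal_records(p$focal)
  germ <- read_germination_trials(p$germination)
  dist <- read_distance_records(p$distances)
  surv <- read_survival_records(p$survival)
  say("read %d focal, %d germination, %d distance, %d survival records",
      nrow(focal), nrow(germ), nrow(dist), nrow(surv))

  all_dispersers <- unique(unlist(lapply(config$sites, `[[`, "dispersers")))
  kernel_samples <- lapply(stats::setNames(nm = all_dispersers), function(d) {
    d_m <- dist$distance_m[dist$disperser == d]
    if (!length(d_m)) {
      stop_sf(sprintf("no dispersal distances recorded for '%s'", d),
              "seedfate_empty_data")
    }
    distance_sample(d_m, d)
  })
  kernels <- lapply(kernel_samples, bin_distances,
                    bin_width = config$bin_width)
  germination <- lapply(
    stats::setNames(nm = c(paste0("defecated_", all_dispersers),
                           "without_pulp", "with_pulp")),
    function(tr) germination_rate(germ, tr)$rate)

  profiles <- list(); curves <- list(); models <- list()
  for (site in names(config$sites)) {
    profiles[[site]] <- seed_fate_profile(focal, site)
    curves[[site]] <- escape_curve(surv, site, years = config$years,
                                   distances_m = config$distances_m)
    site_disp <- union(config$sites[[site]]$dispersers,
                       names(profiles[[site]]$swallowed_by))
    pathways <- lapply(site_disp, function(d) {
      seed_fate_pathway(d, removal_probability(profiles[[site]], d),
                        germination[[paste0("defecated_", d)]], kernels[[d]])
    })
    pathways <- c(pathways, list(
      seed_fate_pathway("spat_out", profiles[[site]]$spat_out,
                        germination[["without_pulp"]],
                        degenerate_kernel(config$bin_width)),
      seed_fate_pathway("undispersed", profiles[[site]]$undispersed,
                        germination[["with_pulp"]],
                        degenerate_kernel(config$bin_width))
    ))
    models[[site]] <- site_recruitment_model(site, pathways, curves[[site]])
    say("site '%s': %d pathways, RS = %.2f%%", site, length(pathways),
        recruitment_success(models[[site]])$rs_percent)
  }
  structure(
    list(models = models, profiles = profiles, kernels = kernels,
         kernel_samples = kernel_samples, germination = germination,
         curves = curves, config = config),
    class = "estimation_result"
  )
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf("estimation_result: %d site model(s)\n", length(x$models)))
  for (m in x$models) {
    cat(sprintf("  %s: RS = %.2f%%\n", m$site,
                recruitment_success(m)$rs_percent))
  }
  invisible(x)
}

#' Run the disperser-loss scenario grid from an estimation result
#'
#' Builds the intact-community base model's scenario grid: escape curves of
#' the configured sites stand in for the seed-predator scenarios, and the
#' seed-fate profiles of communities already lacking the lost dispersers
#' supply the compensation rewiring.
#'
#' @param est an `"estimation_result"` from [run_estimation()].
#' @param config configuration list; defaults to the one stored in `est`.
#' @param out_dir optional directory; when given, the grid is written as
#'   CSV and JSON, a bubble-plot PDF is rendered, and each site model is
#'   serialized to YAML.
#' @return a [scenario_grid()] result.
#' @export
run_scenarios <- function(est, config = est$config, out_dir = NULL) {
  stopifnot(inherits(est, "estimation_result"))
  sc <- config$scenario
  base <- est$models[[sc$base_site]]
  if (is.null(base)) {
    stop_sf(sprintf("base site '%s' was not estimated", sc$base_site),
            "seedfate_config_error")
  }
  curves <- lapply(sc$predator_curves, function(site) {
    cur <- est$curves[[site]]
    if (is.null(cur)) {
      stop_sf(sprintf("predator scenario maps to unestimated site '%s'", site),
              "seedfate_config_error")
    }
    cur
  })
  comp <- lapply(sc$compensation_sources, function(site) est$profiles[[site]])
  grid <- scenario_grid(base, sc$loss_order, curves,
                        compensation_profiles = comp,
                        reference_scenario = sc$reference_scenario %||%
                          names(curves)[1])
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_scenario_grid(grid, out_dir)
    grDevices::pdf(file.path(out_dir, "scenario_grid.pdf"), width = 7,
                   height = 4)
    plot(grid)
    grDevices::dev.off()
    for (m in est$models) {
      model_to_yaml(m, file.path(out_dir, paste0("model_", m$site, ".yaml")))
    }
  }
  grid
}
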