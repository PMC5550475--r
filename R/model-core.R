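#' Map continuous distances to experimental survival classes
#'
#' The survival experiments place seeds at four fixed distances (5, 15, 30,
#' 50 m) while dispersal kernels are continuous; this step function assigns
#' every distance to the experimental class whose station is nearest, with
#' class boundaries halfway between stations (10, 22.5 and 40 m by default)
#' and distances beyond the farthest station clamped to the last class.
#' Long-distance dispersal therefore confers no modelled survival benefit
#' beyond the range of the experiment.
#'
#' @param distance_m numeric vector of distances in metres; must be
#'   non-negative.
#' @param boundaries strictly increasing class boundaries; a distance `d`
#'   falls in class `k` when `boundaries[k - 1] <= d < boundaries[k]`.
#' @return integer vector of class indices in `1:(length(boundaries) + 1)`.
#' @export
#' @examples
#' distance_class(c(5, 11, 80))  # 1, 2, 4
distance_class <- function(distance_m, boundaries = c(10, 22.5, 40)) {
  if (anyNA(distance_m) || any(distance_m < 0)) {
    stop_sf("distances must be non-negative", "seedfate_validation_error")
  }
  stopifnot(all(diff(boundaries) > 0))
  findInterval(distance_m, boundaries) + 1L
}

# aggregate a kernel's probability mass into the escape curve's distance
# classes via the class-mapping rule applied to bin midpoints
kernel_class_mass <- function(kernel, escape, boundaries = c(10, 22.5, 40)) {
  n_class <- length(escape$survival)
  if (length(boundaries) != n_class - 1L) {
    stop_sf(sprintf(
      "class mapping has %d boundaries but the escape curve has %d classes",
      length(boundaries), n_class), "seedfate_class_map_error")
  }
  mids <- kernel_midpoints(kernel)
  if (any(mids < 0)) {
    stop_sf(sprintf("kernel bin starting at %g m has a negative midpoint",
                    kernel$bin_edges[which(mids < 0)[1]]),
            "seedfate_class_map_error")
  }
  cls <- distance_class(mids, boundaries)
  vapply(seq_len(n_class), function(k) sum(kernel$probs[cls == k]), numeric(1))
}

#' Contribution of one seed-fate pathway to recruitment success
#'
#' One summand of the recruitment equation: `100 * P_s * G_s * sum_m(D_sm *
#' T_m)`, with the kernel mass `D_sm` aggregated into the escape curve's
#' distance classes before being weighted by survival.
#'
#' @param pathway a [seed_fate_pathway()].
#' @param escape an escape curve ([new_escape_curve()] or [escape_curve()]).
#' @param boundaries distance-class boundaries passed to [distance_class()].
#' @return the pathway's contribution to recruitment success, in percent of
#'   the annual crop.
#' @export
#' @examples
#' k <- degenerate_kernel()
#' e <- new_escape_curve(c(0.25, 0.3, 0.35, 0.4))
#' pathway_contribution(seed_fate_pathway("a", 0.5, 0.8, k), e)  # 10
pathway_contribution <- function(pathway, escape, boundaries = c(10, 22.5, 40)) {
  stopifnot(inherits(pathway, "seed_fate_pathway"),
            inherits(escape, "escape_curve"))
  mass <- kernel_class_mass(pathway$kernel, escape, boundaries)
  100 * pathway$removal_fraction * pathway$germination_prob *
    sum(mass * escape$survival)
}

#' Recruitment success of a site model
#'
#' Computes the expected percentage of one year's seed crop that yields
#' seedlings alive after one year, as the sum over seed-fate pathways of
#' removal probability x germination probability x kernel-weighted survival.
#'
#' @param model a [site_recruitment_model()].
#' @param boundaries distance-class boundaries passed to [distance_class()].
#' @return an object of class `"recruitment_result"` with fields
#'   `rs_percent` (recruitment success in percent), `pathway_contributions`
#'   (named, absolute, summing to `rs_percent`) and `shares` (fractions of
#'   `rs_percent`, `NA` when recruitment is zero).
#' @export
recruitment_success <- function(model, boundaries = c(10, 22.5, 40)) {
  stopifnot(inherits(model, "site_recruitment_model"))
  contrib <- vapply(model$pathways, pathway_contribution, numeric(1),
                    escape = model$escape, boundaries = boundaries)
  rs <- sum(contrib)
  shares <- if (rs > 0) contrib / rs else rep(NA_real_, length(contrib))
  structure(
    list(site = model$site, rs_percent = rs,
         pathway_contributions = contrib,
         shares = stats::setNames(shares, names(contrib))),
    class = "recruitment_result"
  )
}

#' @export
print.recruitment_result <- function(x, ...) {
  cat(sprintf("recruitment success [site %s]: %.2f%% of the annual crop\n",
              x$site, x$rs_percent))
  print(data.frame(pathway = names(x$pathway_contributions),
                   contribution_percent = round(x$pathway_contributions, 4),
                   share = round(x$shares, 4), row.names = NULL))
  invisible(x)
}

#' Per-pathway shares of recruitment success
#'
#' Normalises pathway contributions by total recruitment success, giving
#' each disperser's relative contribution to recruitment.
#'
#' @param result a `"recruitment_result"` from [recruitment_success()].
#' @return named numeric vector of shares summing to 1.
#' @export
contribution_shares <- function(result) {
  stopifnot(inherits(result, "recruitment_result"))
  if (result$rs_percent <= 0) {
    stop_sf("shares are undefined: recruitment success is zero",
            "seedfate_undefined_shares")
  }
  result$pathway_contributions / result$rs_percent
}

#' Per-seed Monte-Carlo estimate of recruitment success
#'
#' Brute-force stochastic counterpart of [recruitment_success()], used as an
#' independent oracle: each simulated seed draws a fate pathway by the
#' removal fractions, germinates with the pathway's germination probability,
#' lands in a distance class drawn from the pathway kernel, and survives its
#' first year with the class's escape-curve probability.
#'
#' @param model a [site_recruitment_model()].
#' @param n_seeds number of seeds to simulate.
#' @param rng_seed integer seed for reproducibility.
#' @param boundaries distance-class boundaries passed to [distance_class()].
#' @return list with `rs_percent` (estimated recruitment success),
#'   `se_percent` (binomial standard error, percent scale) and `n_seeds`.
#' @export
monte_carlo_rs <- function(model, n_seeds, rng_seed = NULL,
                           boundaries = c(10, 22.5, 40)) {
  stopifnot(inherits(model, "site_recruitment_model"), n_seeds >= 1)
  with_seed(rng_seed, {
    p_fate <- removal_fractions(model)
    fate <- sample.int(length(p_fate), n_seeds, replace = TRUE, prob = p_fate)
    surv <- logical(n_seeds)
    for (i in seq_along(model$pathways)) {
      idx <- which(fate == i)
      if (!length(idx)) next
      pw <- model$pathways[[i]]
      mass <- kernel_class_mass(pw$kernel, model$escape, boundaries)
      cls <- sample.int(length(mass), length(idx), replace = TRUE, prob = mass)
      germinated <- stats::runif(length(idx)) < pw$germination_prob
      survived <- stats::runif(length(idx)) < model$escape$survival[cls]
      surv[idx] <- germinated & survived
    }
    p_hat <- mean(surv)
    list(rs_percent = 100 * p_hat,
         se_percent = 100 * sqrt(p_hat * (1 - p_hat) / n_seeds),
         n_seeds = as.integer(n_seeds))
  })
}

# ---- serialization ----------------------------------------------------------

model_as_list <- function(model) {
  list(
    site = model$site,
    pathways = lapply(unname(model$pathways), function(pw) list(
      label = pw$label,
      removal_fraction = pw$removal_fraction,
      germination_prob = pw$germination_prob,
      kernel = list(bin_edges = pw$kernel$bin_edges,
                    probs = pw$kernel$probs,
                    sample_size = pw$kernel$sample_size)
    )),
    escape = list(site = model$escape$site,
                  years = model$escape$years,
                  distances_m = model$escape$distances_m,
                  survival = model$escape$survival)
  )
}

model_from_list <- function(x) {
  pathways <- lapply(x$pathways, function(pw) {
    edges <- as.numeric(pw$kernel$bin_edges)
    seed_fate_pathway(
      pw$label, pw$removal_fraction, pw$germination_prob,
      distance_kernel(as.numeric(pw$kernel$probs),
                      bin_width = diff(edges[1:2]), start = edges[1],
                      sample_size = pw$kernel$sample_size %||% 0)
    )
  })
  site_recruitment_model(
    x$site, pathways,
    new_escape_curve(as.numeric(x$escape$survival),
                     distances_m = as.numeric(x$escape$distances_m),
                     site = x$escape$site %||% NA_character_,
                     years = as.integer(unlist(x$escape$years)))
  )
}

#' Write a site model to a YAML document
#'
#' The document round-trips losslessly through [model_from_yaml()].
#'
#' @param model a [site_recruitment_model()].
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
model_to_yaml <- function(model, path) {
  stopifnot(inherits(model, "site_recruitment_model"))
  yaml::write_yaml(model_as_list(model), path, precision = 15)
  invisible(path)
}

#' Read a site model from a YAML document
#'
#' @param path file written by [model_to_yaml()].
#' @return a validated [site_recruitment_model()].
#' @export
model_from_yaml <- function(path) {
  model_from_list(yaml::read_yaml(path))
}
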