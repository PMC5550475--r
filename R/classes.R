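#' Binned dispersal-distance kernel
#'
#' A dispersal kernel discretised into uniform distance bins. Bin `m` covers
#' the half-open interval `[bin_edges[m], bin_edges[m + 1])`; `probs[m]` is
#' the probability mass deposited in that bin (the `D_sm` term of the
#' recruitment model). Probabilities must sum to one.
#'
#' @param probs numeric vector of per-bin probability mass; must be
#'   non-negative and sum to 1 within `1e-9`.
#' @param bin_width width of each bin in metres (default 5, the binning used
#'   throughout the package).
#' @param start left edge of the first bin in metres (default 0).
#' @param sample_size number of underlying observed dispersal events; use 0
#'   for analytic kernels.
#' @return an object of class `"distance_kernel"` with fields `bin_edges`,
#'   `probs` and `sample_size`.
#' @seealso [bin_distances()] to build a kernel from raw distances,
#'   [degenerate_kernel()] for all mass in the first bin.
#' @export
#' @examples
#' distance_kernel(c(0.5, 0.3, 0.2))
distance_kernel <- function(probs, bin_width = 5, start = 0, sample_size = 0) {
  stopifnot(is.numeric(probs), length(probs) >= 1, bin_width > 0)
  if (anyNA(probs) || any(probs < 0)) {
    stop_sf("kernel probabilities must be non-negative", "seedfate_validation_error")
  }
  if (abs(sum(probs) - 1) > 1e-9) {
    stop_sf(sprintf("kernel probabilities must sum to 1 (got %.12f)", sum(probs)),
            "seedfate_validation_error")
  }
  edges <- start + bin_width * (0:length(probs))
  structure(
    list(bin_edges = edges, probs = as.numeric(probs),
         sample_size = as.integer(sample_size)),
    class = "distance_kernel"
  )
}

#' @export
print.distance_kernel <- function(x, ...) {
  cat(sprintf("distance_kernel: %d bins of %g m (n = %d events)\n",
              length(x$probs), diff(x$bin_edges[1:2]), x$sample_size))
  invisible(x)
}

#' Degenerate kernel concentrated in the first distance bin
#'
#' Used for seed-fate pathways that leave seeds under or next to the parent
#' crown ("spat out", "undispersed"): all probability mass falls in the
#' nearest bin, so such seeds experience the survival measured at the
#' closest experimental station.
#'
#' @param bin_width bin width in metres.
#' @param n_bins number of bins (mass beyond the first is zero).
#' @return a `"distance_kernel"`.
#' @export
degenerate_kernel <- function(bin_width = 5, n_bins = 1) {
  distance_kernel(c(1, rep(0, n_bins - 1)), bin_width = bin_width)
}

#' Width of the bins of a distance kernel
#' @param kernel a `"distance_kernel"`.
#' @return bin width in metres.
#' @export
kernel_bin_width <- function(kernel) {
  stopifnot(inherits(kernel, "distance_kernel"))
  diff(kernel$bin_edges[1:2])
}

#' Midpoints of the bins of a distance kernel
#' @param kernel a `"distance_kernel"`.
#' @return numeric vector of bin midpoints in metres.
#' @export
kernel_midpoints <- function(kernel) {
  stopifnot(inherits(kernel, "distance_kernel"))
  (kernel$bin_edges[-1] + kernel$bin_edges[-length(kernel$bin_edges)]) / 2
}

#' Re-aggregate a kernel to a coarser bin width
#'
#' The new width must be an integer multiple of the current width; mass is
#' conserved exactly.
#'
#' @param kernel a `"distance_kernel"`.
#' @param new_width target bin width in metres.
#' @return a `"distance_kernel"` at the coarser resolution.
#' @export
rebin_kernel <- function(kernel, new_width) {
  w <- kernel_bin_width(kernel)
  k <- new_width / w
  if (abs(k - round(k)) > 1e-9 || k < 1) {
    stop_sf("new_width must be an integer multiple of the current bin width",
            "seedfate_validation_error")
  }
  k <- as.integer(round(k))
  grp <- (seq_along(kernel$probs) - 1L) %/% k
  probs <- as.numeric(tapply(kernel$probs, grp, sum))
  distance_kernel(probs, bin_width = new_width, start = kernel$bin_edges[1],
                  sample_size = kernel$sample_size)
}

#' One route a seed can take through the dispersal process
#'
#' A seed-fate pathway couples the fraction of the annual crop entering the
#' route (`P_s`, seed removal), the germination probability conditional on
#' that handling (`G_s`), and the dispersal-distance kernel (`D_sm`).
#' Reserved labels `"spat_out"` and `"undispersed"` denote the two
#' non-dispersed routes; by convention they carry a degenerate kernel.
#'
#' @param label pathway identifier: a disperser name, `"spat_out"` or
#'   `"undispersed"`.
#' @param removal_fraction fraction of the crop entering this pathway, in
#'   `[0, 1]`.
#' @param germination_prob germination probability in `[0, 1]`.
#' @param kernel a `"distance_kernel"`.
#' @return an object of class `"seed_fate_pathway"`.
#' @export
#' @examples
#' seed_fate_pathway("muriqui", 0.4, 0.8, distance_kernel(c(0.2, 0.8)))
seed_fate_pathway <- function(label, removal_fraction, germination_prob, kernel) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  assert_prob(removal_fraction, sprintf("removal_fraction of pathway '%s'", label))
  assert_prob(germination_prob, sprintf("germination_prob of pathway '%s'", label))
  if (!inherits(kernel, "distance_kernel")) {
    stop_sf(sprintf("pathway '%s' needs a distance_kernel", label),
            "seedfate_validation_error")
  }
  structure(
    list(label = label, removal_fraction = as.numeric(removal_fraction),
         germination_prob = as.numeric(germination_prob), kernel = kernel),
    class = "seed_fate_pathway"
  )
}

#' @export
print.seed_fate_pathway <- function(x, ...) {
  cat(sprintf("seed_fate_pathway '%s': P = %.4f, G = %.4f, %d kernel bins\n",
              x$label, x$removal_fraction, x$germination_prob,
              length(x$kernel$probs)))
  invisible(x)
}

#' Escape curve: seed survival by distance from the parent tree
#'
#' One-year survival probabilities `T_m` of dispersed seeds at the
#' experimental distance classes (by default 5, 15, 30 and 50 m). The
#' increase of survival with distance is the escape component of
#' distance-dependent (Janzen-Connell) mortality; a flat or declining curve
#' indicates predator communities that remove seeds at all distances.
#'
#' @param survival numeric vector of survival probabilities, one per
#'   distance class.
#' @param distances_m the experimental distances in metres (default
#'   `c(5, 15, 30, 50)`); must match `survival` in length and be strictly
#'   increasing.
#' @param site site identifier.
#' @param years integer vector of years pooled into the curve.
#' @return an object of class `"escape_curve"`.
#' @seealso [escape_curve()] to estimate a curve from survival records.
#' @export
new_escape_curve <- function(survival, distances_m = c(5, 15, 30, 50),
                             site = NA_character_, years = integer()) {
  assert_prob(survival, "escape-curve survival")
  stopifnot(length(survival) == length(distances_m),
            all(diff(distances_m) > 0))
  structure(
    list(site = site, years = years, distances_m = as.numeric(distances_m),
         survival = as.numeric(survival)),
    class = "escape_curve"
  )
}

#' @export
print.escape_curve <- function(x, ...) {
  cat(sprintf("escape_curve [site %s%s]\n", x$site,
              if (length(x$years)) paste0(", years ", paste(x$years, collapse = "/")) else ""))
  print(stats::setNames(round(x$survival, 4), paste0(x$distances_m, "m")))
  invisible(x)
}

#' Full recruitment model of one site
#'
#' Bundles the complete seed-fate pathway set of a site (its dispersers plus
#' the spat-out and undispersed routes) with the site's escape curve. The
#' pathway removal fractions must cover the whole crop: every seed has
#' exactly one fate, so they sum to one.
#'
#' @param site site identifier.
#' @param pathways list of [seed_fate_pathway()] objects with unique labels
#'   whose `removal_fraction`s sum to 1 within `1e-9`.
#' @param escape an `"escape_curve"`.
#' @return an object of class `"site_recruitment_model"`.
#' @export
site_recruitment_model <- function(site, pathways, escape) {
  stopifnot(is.list(pathways), length(pathways) >= 1)
  if (!all(vapply(pathways, inherits, logical(1), "seed_fate_pathway"))) {
    stop_sf("pathways must all be seed_fate_pathway objects",
            "seedfate_validation_error")
  }
  labels <- vapply(pathways, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop_sf("pathway labels must be unique", "seedfate_validation_error")
  }
  total <- sum(vapply(pathways, `[[`, numeric(1), "removal_fraction"))
  if (abs(total - 1) > 1e-9) {
    stop_sf(sprintf(
      "pathway removal fractions must sum to 1 (got %.12f): every seed has exactly one fate",
      total), "seedfate_validation_error")
  }
  if (!inherits(escape, "escape_curve")) {
    stop_sf("escape must be an escape_curve", "seedfate_validation_error")
  }
  names(pathways) <- labels
  structure(
    list(site = site, pathways = pathways, escape = escape),
    class = "site_recruitment_model"
  )
}

#' @export
print.site_recruitment_model <- function(x, ...) {
  cat(sprintf("site_recruitment_model [site %s]: %d pathways\n",
              x$site, length(x$pathways)))
  p <- vapply(x$pathways, `[[`, numeric(1), "removal_fraction")
  g <- vapply(x$pathways, `[[`, numeric(1), "germination_prob")
  print(data.frame(pathway = names(x$pathways), removal = round(p, 4),
                   germination = round(g, 4), row.names = NULL))
  invisible(x)
}

#' Pathway labels of a site model
#' @param model a `"site_recruitment_model"`.
#' @return character vector of pathway labels.
#' @export
pathway_labels <- function(model) {
  stopifnot(inherits(model, "site_recruitment_model"))
  names(model$pathways)
}

#' Disperser labels of a site model
#'
#' All pathway labels except the reserved non-dispersed routes.
#' @param model a `"site_recruitment_model"`.
#' @return character vector of disperser names.
#' @export
dispersers <- function(model) {
  setdiff(pathway_labels(model), c("spat_out", "undispersed"))
}

#' Removal fractions of a site model
#' @param model a `"site_recruitment_model"`.
#' @return named numeric vector of `P_s` per pathway.
#' @export
removal_fractions <- function(model) {
  stopifnot(inherits(model, "site_recruitment_model"))
  vapply(model$pathways, `[[`, numeric(1), "removal_fraction")
}
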