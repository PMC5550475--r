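#' Collect a dispersal-distance sample
#'
#' @param distances_m numeric vector of dispersal distances to the nearest
#'   conspecific, in metres, all non-negative.
#' @param disperser disperser name.
#' @return object of class `"distance_sample"` with fields `disperser`,
#'   `distances_m`, `n`.
#' @export
distance_sample <- function(distances_m, disperser = NA_character_) {
  if (!length(distances_m) || anyNA(distances_m) || any(distances_m < 0)) {
    stop_sf("distances must be a non-empty vector of non-negative values",
            "seedfate_validation_error")
  }
  structure(
    list(disperser = disperser, distances_m = as.numeric(distances_m),
         n = length(distances_m)),
    class = "distance_sample"
  )
}

#' Bin dispersal distances into a histogram kernel
#'
#' Half-open bins `[k * w, (k + 1) * w)` of uniform width starting at zero;
#' a distance exactly on an edge belongs to the upper bin. Bins extend far
#' enough to cover the maximum observed distance, and probabilities are
#' relative frequencies, so mass is conserved exactly.
#'
#' @param sample a [distance_sample()] or numeric vector of distances.
#' @param bin_width bin width in metres (default 5).
#' @return a [distance_kernel()] with `sample_size` set to `n`.
#' @export
#' @examples
#' bin_distances(c(3, 7, 12))$probs  # 1/3 in each of the first three bins
bin_distances <- function(sample, bin_width = 5) {
  if (is.numeric(sample)) sample <- distance_sample(sample)
  stopifnot(inherits(sample, "distance_sample"), bin_width > 0)
  d <- sample$distances_m
  idx <- floor(d / bin_width) + 1L
  n_bins <- max(idx)
  counts <- tabulate(idx, nbins = n_bins)
  distance_kernel(counts / sample$n, bin_width = bin_width,
                  sample_size = sample$n)
}

#' Smoothing-spline fit to a binned dispersal kernel
#'
#' Fits a cubic smoothing spline to the per-bin empirical densities at bin
#' midpoints, evaluates it on a fine distance grid, clips negative values
#' to zero and renormalises so the curve integrates to one over the grid.
#' With fewer than four occupied bins a spline is not identifiable and the
#' empirical histogram is returned instead, with a warning.
#'
#' @param kernel a [distance_kernel()].
#' @param smoothing `"auto"` to select the smoothing parameter by
#'   generalized cross-validation, or a numeric `spar` value as in
#'   [stats::smooth.spline()].
#' @param grid_n number of grid points.
#' @return object of class `"smooth_kernel"` with fields `grid_m`,
#'   `density` (per metre, integrating to 1), `spar` (selected smoothing),
#'   `degenerate` (`TRUE` when the histogram fallback was used).
#' @export
smooth_kernel <- function(kernel, smoothing = "auto", grid_n = 200) {
  stopifnot(inherits(kernel, "distance_kernel"))
  w <- kernel_bin_width(kernel)
  mids <- kernel_midpoints(kernel)
  dens <- kernel$probs / w
  grid <- seq(kernel$bin_edges[1], kernel$bin_edges[length(kernel$bin_edges)],
              length.out = grid_n)
  histogram_on_grid <- function() {
    idx <- pmin(findInterval(grid, kernel$bin_edges,
                             rightmost.closed = TRUE), length(dens))
    idx[idx < 1L] <- 1L
    dens[idx]
  }
  occupied <- sum(kernel$probs > 0)
  if (occupied < 4) {
    warning(sprintf(
      "only %d occupied bin(s): returning the empirical histogram instead of a spline fit",
      occupied), call. = FALSE)
    y <- histogram_on_grid()
    y <- normalize_density(y, grid)
    return(structure(list(grid_m = grid, density = y, spar = NA_real_,
                          degenerate = TRUE), class = "smooth_kernel"))
  }
  fit <- if (identical(smoothing, "auto")) {
    stats::smooth.spline(mids, dens, cv = FALSE)
  } else {
    stats::smooth.spline(mids, dens, spar = smoothing)
  }
  y <- pmax(stats::predict(fit, grid)$y, 0)
  y <- normalize_density(y, grid)
  structure(list(grid_m = grid, density = y, spar = fit$spar,
                 degenerate = FALSE), class = "smooth_kernel")
}

# trapezoid renormalisation to unit mass on the grid
normalize_density <- function(y, grid) {
  area <- sum(diff(grid) * (y[-1] + y[-length(y)]) / 2)
  if (area <= 0) {
    stop_sf("smoothed density has zero mass on its grid",
            "seedfate_degenerate_fit")
  }
  y / area
}

#' @export
print.smooth_kernel <- function(x, ...) {
  cat(sprintf("smooth_kernel on [%g, %g] m, %d grid points%s\n",
              min(x$grid_m), max(x$grid_m), length(x$grid_m),
              if (x$degenerate) " (histogram fallback)" else
                sprintf(", spar = %.3f", x$spar)))
  invisible(x)
}

#' Bootstrap envelope around a smoothed dispersal kernel
#'
#' Resamples the distance sample with replacement, re-bins each replicate
#' onto the original bin grid, re-smooths it with the smoothing parameter
#' selected for the point fit, and returns pointwise quantile curves across
#' replicates. Fully reproducible under a fixed seed.
#'
#' @param sample a [distance_sample()] with `n >= 2`.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param quantiles lower/upper envelope quantiles (default 2.5% and
#'   97.5%).
#' @param rng_seed integer seed.
#' @param bin_width bin width in metres.
#' @param smoothing smoothing setting for the point fit (see
#'   [smooth_kernel()]).
#' @return object of class `"kernel_fit"`: `kernel` (the point histogram),
#'   `smooth` (the point [smooth_kernel()]), `boot_lower`, `boot_upper`
#'   (envelope densities on the same grid), `n_boot`, `quantiles`,
#'   `rng_seed`.
#' @export
bootstrap_kernel <- function(sample, n_boot = 1000,
                             quantiles = c(0.025, 0.975), rng_seed = NULL,
                             bin_width = 5, smoothing = "auto") {
  stopifnot(inherits(sample, "distance_sample"), sample$n >= 2, n_boot >= 1,
            length(quantiles) == 2, quantiles[1] <= quantiles[2])
  kernel <- bin_distances(sample, bin_width)
  point <- suppressWarnings(smooth_kernel(kernel, smoothing))
  spar_fixed <- if (point$degenerate) smoothing else point$spar
  n_bins <- length(kernel$probs)
  with_seed(rng_seed, {
    curves <- matrix(NA_real_, n_boot, length(point$grid_m))
    for (b in seq_len(n_boot)) {
      d <- sample(sample$distances_m, sample$n, replace = TRUE)
      idx <- floor(d / bin_width) + 1L
      probs <- tabulate(idx, nbins = n_bins) / sample$n
      k_b <- distance_kernel(probs, bin_width = bin_width,
                             sample_size = sample$n)
      curves[b, ] <- suppressWarnings(
        smooth_kernel(k_b, smoothing = spar_fixed)$density)
    }
    lo <- apply(curves, 2, stats::quantile, probs = quantiles[1], names = FALSE)
    hi <- apply(curves, 2, stats::quantile, probs = quantiles[2], names = FALSE)
    structure(
      list(kernel = kernel, smooth = point, boot_lower = lo, boot_upper = hi,
           n_boot = as.integer(n_boot), quantiles = quantiles,
           rng_seed = rng_seed),
      class = "kernel_fit"
    )
  })
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat(sprintf(
    "kernel_fit: n = %d events, %d bootstrap replicates, %g-%g%% envelope\n",
    x$kernel$sample_size, x$n_boot, 100 * x$quantiles[1], 100 * x$quantiles[2]))
  invisible(x)
}

#' Summary moments of a dispersal-distance sample
#'
#' @param sample a [distance_sample()] or numeric vector.
#' @return list with `mean_m`, `sd_m` (n - 1 denominator; `NA` for a single
#'   observation) and `n`.
#' @export
#' @examples
#' kernel_summary(c(0, 10))  # mean 5, sd ~7.071
kernel_summary <- function(sample) {
  if (is.numeric(sample)) sample <- distance_sample(sample)
  stopifnot(inherits(sample, "distance_sample"))
  list(mean_m = mean(sample$distances_m),
       sd_m = if (sample$n >= 2) stats::sd(sample$distances_m) else NA_real_,
       n = sample$n)
}

#' Compare dispersal distances among dispersers
#'
#' One-way ANOVA of dispersal distance on disperser identity, with pairwise
#' Tukey-Kramer comparisons (honestly significant difference adjusted for
#' unequal group sizes), as used to contrast long- and short-distance
#' dispersers.
#'
#' @param samples named list of [distance_sample()] objects (or numeric
#'   vectors), one per disperser.
#' @return list with `f_statistic`, `df_between`, `df_within`, `p_value`,
#'   `n`, `group_means`, and `pairwise` (data.frame of pairwise mean
#'   differences with Tukey-adjusted p-values).
#' @export
distance_anova <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 2, !is.null(names(samples)))
  values <- lapply(samples, function(s) {
    if (inherits(s, "distance_sample")) s$distances_m else as.numeric(s)
  })
  g <- length(values)
  n_i <- vapply(values, length, integer(1))
  n <- sum(n_i)
  all_y <- unlist(values, use.names = FALSE)
  grand <- mean(all_y)
  means <- vapply(values, mean, numeric(1))
  ss_between <- sum(n_i * (means - grand)^2)
  ss_within <- sum(vapply(seq_len(g), function(i) {
    sum((values[[i]] - means[i])^2)
  }, numeric(1)))
  df_b <- g - 1L
  df_w <- n - g
  ms_w <- ss_within / df_w
  f <- (ss_between / df_b) / ms_w
  p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  pairs <- utils::combn(names(values), 2)
  pairwise <- data.frame(
    a = pairs[1, ], b = pairs[2, ],
    diff = means[pairs[1, ]] - means[pairs[2, ]],
    row.names = NULL
  )
  se <- sqrt(ms_w / 2 * (1 / n_i[pairs[1, ]] + 1 / n_i[pairs[2, ]]))
  q_stat <- abs(pairwise$diff) / se
  pairwise$p_adj <- stats::ptukey(q_stat, nmeans = g, df = df_w,
                                  lower.tail = FALSE)
  list(f_statistic = f, df_between = df_b, df_within = df_w, p_value = p,
       n = n, group_means = means, pairwise = pairwise)
}
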