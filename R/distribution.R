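#' Summarize a relative-orientation distribution
#'
#' Gaussian kernel density estimate of the acute-angle samples (the violin
#' outline), box statistics, and the perpendicular fraction — the share of
#' samples with Delta > 45 degrees, the natural bisector between "parallel"
#' and "perpendicular" to the invasive front.
#'
#' The default bandwidth is the normal-reference (Silverman) rule
#' `1.06 * sd * n^(-1/5)` ([stats::bw.nrd]), matching MATLAB's `ksdensity`
#' default; the KDE is unbounded by default (no boundary correction), with an
#' optional reflected variant that folds mass back at 0 and 90 degrees.
#'
#' @param samples acute angles in degrees in \[0, 90\] (>= 1 value).
#' @param kde_bandwidth `"silverman"` (default) or a numeric bandwidth in
#'   degrees.
#' @param reflect logical; reflect the KDE at the 0 and 90 degree boundaries.
#' @param n_grid number of density grid points (default 2048).
#' @return object of class `orientation_distribution`: list with `samples`,
#'   `n`, `grid`, `density`, `bandwidth`, `median`, `q1`, `q3`, `whiskers`
#'   (Tukey, 1.5 IQR capped at the data range) and `perpendicular_fraction`.
#' @export
distribution_summary <- function(samples, kde_bandwidth = "silverman",
                                 reflect = FALSE, n_grid = 2048) {
  samples <- as.numeric(samples)
  samples <- samples[!is.na(samples)]
  if (length(samples) < 1) stop("no samples", call. = FALSE)
  if (any(samples < 0 | samples > 90))
    stop("samples must lie in [0, 90]", call. = FALSE)
  bw <- if (identical(kde_bandwidth, "silverman")) {
    if (length(samples) > 1 && stats::sd(samples) > 0)
      stats::bw.nrd(samples) else 1
  } else as.numeric(kde_bandwidth)
  # grid spans [0, 90] and the KDE tails (4 sd) so the density integrates to 1
  lo <- min(0, min(samples) - 4 * bw)
  hi <- max(90, max(samples) + 4 * bw)
  if (reflect) { lo <- 0; hi <- 90 }
  dens <- stats::density(samples, bw = bw, from = lo, to = hi, n = n_grid)
  y <- dens$y
  if (reflect) {
    refl0 <- stats::density(-samples, bw = bw, from = lo, to = hi, n = n_grid)
    refl90 <- stats::density(180 - samples, bw = bw, from = lo, to = hi,
                             n = n_grid)
    y <- y + refl0$y + refl90$y
  }
  q <- stats::quantile(samples, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  whisk <- c(max(min(samples), q[1] - 1.5 * iqr),
             min(max(samples), q[3] + 1.5 * iqr))
  structure(list(samples = samples, n = length(samples),
                 grid = dens$x, density = y, bandwidth = bw,
                 median = q[2], q1 = q[1], q3 = q[3], whiskers = whisk,
                 perpendicular_fraction = mean(samples > 45)),
            class = "orientation_distribution")
}

#' @export
print.orientation_distribution <- function(x, ...) {
  cat(sprintf(paste0("<orientation_distribution> n = %d, median = %.1f deg,",
                     " IQR = [%.1f, %.1f], perpendicular fraction = %.3f\n"),
              x$n, x$median, x$q1, x$q3, x$perpendicular_fraction))
  invisible(x)
}

#' Compare relative-orientation distributions of two invasion phenotypes
#'
#' Contrasts a "low" (expected tangential collagen) and a "high" (expected
#' radial collagen) phenotype: reports both medians and perpendicular
#' fractions, their differences (high minus low), and whether the high
#' phenotype has the larger perpendicular fraction.
#'
#' @param dist_low,dist_high [orientation_distribution][distribution_summary]
#'   objects.
#' @return object of class `phenotype_comparison` (a list).
#' @export
compare_phenotypes <- function(dist_low, dist_high) {
  stopifnot(inherits(dist_low, "orientation_distribution"),
            inherits(dist_high, "orientation_distribution"))
  structure(list(
    median_low = dist_low$median, median_high = dist_high$median,
    median_diff = dist_high$median - dist_low$median,
    perpendicular_fraction_low = dist_low$perpendicular_fraction,
    perpendicular_fraction_high = dist_high$perpendicular_fraction,
    perpendicular_fraction_diff =
      dist_high$perpendicular_fraction - dist_low$perpendicular_fraction,
    high_more_perpendicular =
      dist_high$perpendicular_fraction > dist_low$perpendicular_fraction),
    class = "phenotype_comparison")
}

#' @export
print.phenotype_comparison <- function(x, ...) {
  cat(sprintf(paste0("<phenotype_comparison>\n",
                     "  median (deg):            low %.1f, high %.1f (diff %+.1f)\n",
                     "  perpendicular fraction:  low %.3f, high %.3f (diff %+.3f)\n",
                     "  high more perpendicular: %s\n"),
              x$median_low, x$median_high, x$median_diff,
              x$perpendicular_fraction_low, x$perpendicular_fraction_high,
              x$perpendicular_fraction_diff, x$high_more_perpendicular))
  invisible(x)
}

#' Violin/box plot of relative-orientation distributions
#'
#' @param distributions named list of
#'   [orientation_distribution][distribution_summary] objects.
#' @return a ggplot object (violin + box, acute angle on the y axis).
#' @export
plot_orientation_violin <- function(distributions) {
  stopifnot(length(distributions) >= 1, !is.null(names(distributions)))
  df <- do.call(rbind, lapply(names(distributions), function(nm) {
    data.frame(group = nm, delta = distributions[[nm]]$samples)
  }))
  df$group <- factor(df$group, levels = names(distributions))
  ggplot2::ggplot(df, ggplot2::aes(x = group, y = delta, fill = group)) +
    ggplot2::geom_violin(trim = FALSE, alpha = 0.7, show.legend = FALSE) +
    ggplot2::geom_boxplot(width = 0.12, outlier.size = 0.4,
                          show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 45, linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::scale_y_continuous(breaks = seq(0, 90, 15)) +
    ggplot2::coord_cartesian(ylim = c(-5, 95)) +
    ggplot2::labs(x = NULL,
                  y = "fiber angle to invasive front (deg)") +
    ggplot2::theme_minimal()
}
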