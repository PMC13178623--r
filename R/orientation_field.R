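#' Ground-truth fiber orientation fields
#'
#' An orientation field holds, for every pixel of an H x W raster, zero, one or
#' two in-plane fiber orientations in \[0, 180) degrees together with a
#' non-negative scattering amplitude per fiber. Pixels with no fiber are
#' background. Fields are the known truth that the phantom renderers
#' ([render_scatter_stack()], [render_pli_stack()], [render_psr_image()]) turn
#' into synthetic measurements.
#'
#' Available kinds:
#' \describe{
#'   \item{`constant`}{every pixel carries one orientation `theta`.}
#'   \item{`smooth_gradient`}{orientation varies linearly with column from
#'     `theta_from` to `theta_to` across the image.}
#'   \item{`two_region_crossing`}{left region carries `theta1`, right region
#'     `theta2`, and a central vertical strip (fraction `overlap` of the
#'     width) carries both, emulating crossing fiber bundles.}
#'   \item{`tumor_phantom`}{a circular "tumor" of radius `radius` at `center`
#'     (x, y) surrounded by a peritumoral collagen band of width `band_width`
#'     pixels. `arrangement = "tangential"` lays fibers along circle tangents
#'     (bearing + 90 mod 180), `"radial"` along radii (bearing mod 180), and
#'     `"mixed"` assigns each band pixel radial orientation with probability
#'     `mixed_fraction` (tangential otherwise), emulating low- vs high-WPOI
#'     collagen arrangements at a tumor invasive front. The returned field
#'     carries the boundary polygon, band mask and radial-pixel mask as
#'     attributes `boundary`, `band` and `radial`.}
#' }
#'
#' @param kind one of `"constant"`, `"smooth_gradient"`,
#'   `"two_region_crossing"`, `"tumor_phantom"`.
#' @param height,width image size in pixels.
#' @param params named list of kind-specific parameters (see Details).
#' @param seed integer seed controlling any randomness (mixed phantom);
#'   identical seeds give identical fields.
#' @return an object of class `orientation_field`: list with `height`,
#'   `width`, `orientations` (H x W x 2 array, degrees, `NA` = no fiber),
#'   `amplitudes` (H x W x 2), `kind`.
#' @examples
#' f <- make_orientation_field("constant", 16, 16, list(theta = 30))
#' table(f$orientations[, , 1])
#' @export
make_orientation_field <- function(kind, height, width, params = list(),
                                   seed = NULL) {
  if (!is.numeric(height) || !is.numeric(width) || height < 1 || width < 1)
    stop("image dimensions must be positive", call. = FALSE)
  kind <- match.arg(kind, c("constant", "smooth_gradient",
                            "two_region_crossing", "tumor_phantom"))
  ori <- array(NA_real_, c(height, width, 2))
  amp <- array(NA_real_, c(height, width, 2))
  extra <- NULL

  check_theta <- function(th, name = "theta") {
    stop_if_not_scalar_number(th, name)
    if (th < 0 || th >= 180)
      stop(sprintf("`%s` must lie in [0, 180)", name), call. = FALSE)
    th
  }

  if (kind == "constant") {
    th <- check_theta(params$theta)
    ori[, , 1] <- th
    amp[, , 1] <- params$amplitude %||% 1
  } else if (kind == "smooth_gradient") {
    t0 <- check_theta(params$theta_from %||% 0, "theta_from")
    t1 <- check_theta(params$theta_to %||% 170, "theta_to")
    cols <- if (width > 1) (seq_len(width) - 1) / (width - 1) else 0
    ori[, , 1] <- matrix(mod180(t0 + cols * (t1 - t0)),
                         height, width, byrow = TRUE)
    amp[, , 1] <- params$amplitude %||% 1
  } else if (kind == "two_region_crossing") {
    th1 <- check_theta(params$theta1, "theta1")
    th2 <- check_theta(params$theta2, "theta2")
    ov <- params$overlap %||% (1 / 3)
    half <- ov / 2
    cols <- (seq_len(width) - 0.5) / width
    left  <- cols <= 0.5 + half
    right <- cols >= 0.5 - half
    ori[, left, 1]  <- th1
    amp[, left, 1]  <- params$amplitude %||% 1
    ori[, right, 2] <- th2
    amp[, right, 2] <- params$amplitude %||% 1
    # pixels carrying only the second fiber: shift it into layer 1
    only2 <- is.na(ori[, , 1]) & !is.na(ori[, , 2])
    o2 <- ori[, , 2]; a2 <- amp[, , 2]
    o1 <- ori[, , 1]; a1 <- amp[, , 1]
    o1[only2] <- o2[only2]; a1[only2] <- a2[only2]
    o2[only2] <- NA; a2[only2] <- NA
    ori[, , 1] <- o1; ori[, , 2] <- o2
    amp[, , 1] <- a1; amp[, , 2] <- a2
  } else { # tumor_phantom
    cx <- params$center[1] %||% ((width - 1) / 2)
    cy <- if (length(params$center) >= 2) params$center[2] else (height - 1) / 2
    r  <- params$radius %||% (min(height, width) / 4)
    bw <- params$band_width %||% (min(height, width) / 8)
    arrangement <- match.arg(params$arrangement %||% "tangential",
                             c("tangential", "radial", "mixed"))
    if (bw <= 0) stop("band_width must be positive", call. = FALSE)
    if (cx - r < 0 || cy - r < 0 || cx + r > width - 1 || cy + r > height - 1)
      stop("tumor boundary must lie fully inside the image", call. = FALSE)
    x <- matrix(seq_len(width) - 1, height, width, byrow = TRUE)
    y <- matrix(seq_len(height) - 1, height, width)
    d <- sqrt((x - cx)^2 + (y - cy)^2)
    band <- d > r & d <= r + bw
    bearing <- vec_orientation(x - cx, y - cy)  # bearing of pixel from center
    radial_map <- matrix(FALSE, height, width)
    if (arrangement == "radial") {
      radial_map <- band
    } else if (arrangement == "mixed") {
      p <- params$mixed_fraction
      stop_if_not_scalar_number(p, "mixed_fraction")
      if (p < 0 || p > 1) stop("mixed_fraction must be in [0, 1]", call. = FALSE)
      radial_map[band] <- with_seed(seed, stats::runif(sum(band)) < p)
    }
    o <- matrix(NA_real_, height, width)
    o[band] <- mod180(bearing[band] + 90)        # tangential default
    o[radial_map] <- bearing[radial_map]          # radial overrides
    ori[, , 1] <- o
    a <- matrix(NA_real_, height, width)
    a[band] <- params$amplitude %||% 1
    amp[, , 1] <- a
    # boundary polygon (anti-clockwise on screen), 1-px chord length
    nv <- max(16L, ceiling(2 * pi * r))
    ang <- seq(0, 2 * pi, length.out = nv + 1)[-(nv + 1)]
    extra <- list(
      boundary = list(curves = list(list(
        closed = TRUE,
        points = cbind(x = cx + r * cos(ang), y = cy - r * sin(ang))))),
      band = band, radial = radial_map,
      center = c(cx, cy), radius = r, band_width = bw
    )
  }

  out <- structure(
    list(height = as.integer(height), width = as.integer(width),
         orientations = ori, amplitudes = amp, kind = kind),
    class = "orientation_field")
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.orientation_field <- function(x, ...) {
  nfib <- rowSums(cbind(c(!is.na(x$orientations[, , 1])),
                        c(!is.na(x$orientations[, , 2]))))
  cat(sprintf("<orientation_field> %d x %d (%s); fibers/pixel: 0:%d 1:%d 2:%d\n",
              x$height, x$width, x$kind,
              sum(nfib == 0), sum(nfib == 1), sum(nfib == 2)))
  invisible(x)
}
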