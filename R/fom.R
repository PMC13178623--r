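# Fiber orientation map rendering: orientation -> hue color wheel.

# Map orientations in [0, 180) to 8-bit RGB via hue = 2 * orientation
# (red 0deg, yellow 30, green 60, cyan 90, blue 120, magenta 150).
orientation_to_rgb <- function(theta) {
  ok <- !is.na(theta)
  out <- matrix(0L, length(theta), 3)
  if (any(ok)) {
    cols <- grDevices::hsv(mod180(theta[ok]) * 2 / 360, 1, 1)
    out[ok, ] <- t(grDevices::col2rgb(cols))
  }
  out
}

#' Colorize an orientation map as a fiber orientation map (FOM)
#'
#' Hue encodes orientation at twice the angle (color wheel: red = 0 degrees,
#' yellow = 30, green = 60, cyan = 90, blue = 120, magenta = 150), at full
#' saturation and value. Invalid and masked pixels are black. Pixels with
#' several orientations are colored by the most prominent pair (layer 1).
#'
#' @param orients an [orientation_map][compute_orientation_map].
#' @param background_mask optional logical H x W matrix; `TRUE` = mask out.
#' @return H x W x 3 integer array, values 0..255.
#' @export
colorize_fom <- function(orients, background_mask = NULL) {
  stopifnot(inherits(orients, "orientation_map"))
  theta <- orients$orientations[, , 1]
  theta[!orients$valid] <- NA
  if (!is.null(background_mask)) theta[background_mask] <- NA
  h <- nrow(theta); w <- ncol(theta)
  array(orientation_to_rgb(c(theta)), c(h, w, 3))
}

#' Mask a FOM by average scattering intensity
#'
#' Background pixels scatter little light at any azimuth; blacking out pixels
#' whose average intensity falls below a threshold removes them. The
#' threshold is either found by Otsu's method on the average map or supplied
#' absolutely.
#'
#' @param fom H x W x 3 RGB array from [colorize_fom()].
#' @param avg average intensity map ([average_intensity_map()]).
#' @param method `"otsu"` (default) or `"absolute"`.
#' @param level threshold for `method = "absolute"`.
#' @return list with `fom` (masked RGB array), `mask` (logical, `TRUE` =
#'   kept foreground) and `threshold` used.
#' @export
mask_by_average_intensity <- function(fom, avg, method = c("otsu", "absolute"),
                                      level = NULL) {
  method <- match.arg(method)
  if (!all(dim(fom)[1:2] == dim(avg)))
    stop("FOM and average map shapes differ", call. = FALSE)
  if (method == "absolute") {
    if (is.null(level))
      stop("`level` is required for method = \"absolute\"", call. = FALSE)
    thr <- level
  } else {
    lo <- min(avg); hi <- max(avg)
    if (hi == lo) {
      thr <- lo  # constant map: nothing below, everything kept
    } else {
      thr01 <- EBImage::otsu(matrix((avg - lo) / (hi - lo),
                                    nrow(avg), ncol(avg)),
                             range = c(0, 1), levels = 256)
      thr <- lo + thr01 * (hi - lo)
    }
  }
  keep <- avg >= thr
  out <- fom
  for (ch in 1:3) {
    m <- out[, , ch]
    m[!keep] <- 0L
    out[, , ch] <- m
  }
  list(fom = out, mask = keep, threshold = thr)
}
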