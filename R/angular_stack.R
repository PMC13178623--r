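#' Angular scattering stack
#'
#' The ComSLI measurement unit: K grayscale frames of the same scene, one per
#' azimuthal illumination angle, with the angles sampled at a constant step
#' over the full circle (e.g. 24 frames every 15 degrees).
#'
#' @param frames H x W x K numeric array (or list of K matrices).
#' @param angles K azimuth angles in degrees, strictly increasing, equally
#'   spaced modulo 360; K >= 8.
#' @param pixel_size optional pixel pitch in micrometers.
#' @return object of class `angular_stack`.
#' @export
angular_stack <- function(frames, angles, pixel_size = NULL) {
  if (is.list(frames)) {
    frames <- array(unlist(frames),
                    c(dim(frames[[1]]), length(frames)))
  }
  if (length(dim(frames)) != 3)
    stop("`frames` must be an H x W x K array", call. = FALSE)
  K <- dim(frames)[3]
  if (K < 8) stop("need at least 8 frames", call. = FALSE)
  if (length(angles) != K)
    stop("angle count does not match frame count", call. = FALSE)
  ord <- order(angles)   # frames may arrive in any order with their labels
  angles <- angles[ord]
  frames <- frames[, , ord, drop = FALSE]
  if (any(diff(angles) <= 0))
    stop("duplicate azimuth angles", call. = FALSE)
  steps <- diff(c(angles, angles[1] + 360))
  if (max(steps) - min(steps) > 1e-9)
    stop("angles must be equally spaced over the full circle", call. = FALSE)
  structure(list(frames = frames, angles = as.numeric(angles),
                 pixel_size = pixel_size),
            class = "angular_stack")
}

#' @export
print.angular_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<angular_stack> %d x %d pixels, %d angles (%g deg step)\n",
              d[1], d[2], d[3], x$angles[2] - x$angles[1]))
  invisible(x)
}

#' Average scattering intensity map
#'
#' Per-pixel arithmetic mean of the intensity across all illumination angles.
#' Tissue scatters at every azimuth while the background does not, so this map
#' doubles as the mask source for background removal
#' ([mask_by_average_intensity()]).
#'
#' @param stack an [angular_stack()].
#' @return H x W numeric matrix.
#' @export
average_intensity_map <- function(stack) {
  stopifnot(inherits(stack, "angular_stack"))
  d <- dim(stack$frames)
  matrix(rowMeans(matrix(stack$frames, d[1] * d[2], d[3])), d[1], d[2])
}

#' Extract the azimuthal intensity profile of one pixel
#'
#' @param stack an [angular_stack()].
#' @param row,col 1-based pixel indices.
#' @return list with `intensity` (length K) and `angles` (degrees).
#' @export
extract_profile <- function(stack, row, col) {
  stopifnot(inherits(stack, "angular_stack"))
  d <- dim(stack$frames)
  if (row < 1 || row > d[1] || col < 1 || col > d[2])
    stop("pixel index out of range", call. = FALSE)
  list(intensity = stack$frames[row, col, ], angles = stack$angles)
}
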