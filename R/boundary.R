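#' Boundary annotations of the tumor invasive front
#'
#' A boundary annotation is a list of curves, each an ordered polyline or
#' polygon of (x, y) pixel coordinates with a `closed` flag. Closed curves
#' need at least 3 vertices, open curves at least 2; consecutive duplicate
#' vertices are rejected.
#'
#' @param points n x 2 matrix of (x, y) vertices, or a list of such curves
#'   (each `list(points =, closed =)`).
#' @param closed logical flag (single curve form).
#' @return object of class `boundary_annotation`: `list(curves = ...)`.
#' @export
boundary_annotation <- function(points, closed = TRUE) {
  if (is.list(points) && !is.null(points$curves)) points <- points$curves
  curves <- if (is.list(points) && !is.matrix(points) && !is.data.frame(points))
    points else list(list(points = points, closed = closed))
  curves <- lapply(curves, function(cv) {
    p <- matrix(as.numeric(as.matrix(cv$points)), ncol = 2)
    if (cv$closed && nrow(p) < 3)
      stop("closed curves need at least 3 vertices", call. = FALSE)
    if (!cv$closed && nrow(p) < 2)
      stop("open curves need at least 2 vertices", call. = FALSE)
    if (any(rowSums(abs(diff(p))) == 0))
      stop("repeated consecutive vertices", call. = FALSE)
    list(points = p, closed = isTRUE(cv$closed))
  })
  structure(list(curves = curves), class = "boundary_annotation")
}

# Vertex sequence with the closing segment appended for closed curves.
curve_path <- function(cv) {
  p <- cv$points
  if (cv$closed) rbind(p, p[1, , drop = FALSE]) else p
}

#' Resample a boundary at constant arc length and estimate tangents
#'
#' The curve is resampled at (approximately) `spacing` pixels of arc length —
#' the spacing is adjusted to divide the total length exactly, so resampled
#' vertices are equally spaced. The tangent at each vertex is the direction
#' of the central difference over `smooth_window` vertices on either side
#' (one-sided at open-curve endpoints), reported as an orientation in
#' \[0, 180) degrees.
#'
#' @param boundary a [boundary_annotation()] (or acceptable input to it).
#' @param spacing target arc-length spacing in pixels (> 0).
#' @param smooth_window half-width, in resampled vertices, of the central
#'   difference (default 1).
#' @return data.frame of class `tangent_field` with columns `x`, `y`,
#'   `tangent_deg`, `curve` (curve index).
#' @export
resample_and_tangents <- function(boundary, spacing, smooth_window = 1) {
  if (!inherits(boundary, "boundary_annotation"))
    boundary <- boundary_annotation(boundary)
  if (spacing <= 0) stop("`spacing` must be positive", call. = FALSE)
  out <- list()
  for (ci in seq_along(boundary$curves)) {
    cv <- boundary$curves[[ci]]
    path <- curve_path(cv)
    seg <- sqrt(rowSums(diff(path)^2))
    len <- c(0, cumsum(seg))
    total <- len[length(len)]
    n <- max(if (cv$closed) 3L else 1L, round(total / spacing))
    s <- if (cv$closed) seq(0, total, length.out = n + 1)[-(n + 1)]
         else seq(0, total, length.out = n + 1)
    px <- stats::approx(len, path[, 1], xout = s, ties = "ordered")$y
    py <- stats::approx(len, path[, 2], xout = s, ties = "ordered")$y
    m <- length(s)
    w <- max(1L, as.integer(smooth_window))
    idx_fwd <- function(i) if (cv$closed) ((i - 1 + w) %% m) + 1 else pmin(i + w, m)
    idx_bwd <- function(i) if (cv$closed) ((i - 1 - w) %% m) + 1 else pmax(i - w, 1)
    i <- seq_len(m)
    dx <- px[idx_fwd(i)] - px[idx_bwd(i)]
    dy <- py[idx_fwd(i)] - py[idx_bwd(i)]
    out[[ci]] <- data.frame(x = px, y = py,
                            tangent_deg = vec_orientation(dx, dy),
                            curve = ci)
  }
  res <- do.call(rbind, out)
  class(res) <- c("tangent_field", "data.frame")
  res
}

# Minimum distance from points (px, py) to a polyline path (n x 2), exact
# point-to-segment distance, vectorized over points.
dist_to_path <- function(px, py, path) {
  dmin <- rep(Inf, length(px))
  for (k in seq_len(nrow(path) - 1)) {
    ax <- path[k, 1]; ay <- path[k, 2]
    bx <- path[k + 1, 1]; by <- path[k + 1, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) rep(0, length(px))
         else pmax(0, pmin(1, ((px - ax) * vx + (py - ay) * vy) / L2))
    d2 <- (px - (ax + t * vx))^2 + (py - (ay + t * vy))^2
    dmin <- pmin(dmin, d2)
  }
  sqrt(dmin)
}

#' Rasterize the peritumoral band around a boundary
#'
#' Marks every pixel whose distance to the boundary curve is at most
#' `band_width`, optionally restricted to the outside of closed curves (the
#' peritumoral side, default).
#'
#' @param boundary a [boundary_annotation()].
#' @param band_width band half-width; pixels, or micrometers when
#'   `units = "um"` (then `pixel_size` is required).
#' @param image_shape c(height, width) of the raster.
#' @param side `"outside"` (default; closed curves only) or `"both"`.
#' @param units `"px"` or `"um"`.
#' @param pixel_size pixel pitch in micrometers (for `units = "um"`).
#' @return logical H x W matrix, `TRUE` inside the band.
#' @export
peritumoral_band <- function(boundary, band_width, image_shape,
                             side = c("outside", "both"), units = c("px", "um"),
                             pixel_size = NULL) {
  side <- match.arg(side); units <- match.arg(units)
  if (!inherits(boundary, "boundary_annotation"))
    boundary <- boundary_annotation(boundary)
  if (band_width <= 0) stop("`band_width` must be positive", call. = FALSE)
  if (units == "um") {
    if (is.null(pixel_size))
      stop("band width in micrometers needs `pixel_size` metadata",
           call. = FALSE)
    band_width <- band_width / pixel_size
  }
  h <- image_shape[1]; w <- image_shape[2]
  px <- c(matrix(seq_len(w) - 1, h, w, byrow = TRUE))
  py <- c(matrix(seq_len(h) - 1, h, w))
  near <- rep(FALSE, h * w)
  inside_any <- rep(FALSE, h * w)
  for (cv in boundary$curves) {
    d <- dist_to_path(px, py, curve_path(cv))
    near <- near | d <= band_width
    if (cv$closed)
      inside_any <- inside_any | points_in_polygon(px, py, cv$points)
  }
  keep <- if (side == "outside") near & !inside_any else near
  matrix(keep, h, w)
}

#' Acute angle between a fiber orientation and a boundary tangent
#'
#' Both arguments are orientations (mod 180). The relative angle is
#' `d = |fiber - tangent| mod 180`, folded to the acute sector:
#' `min(d, 180 - d)`, in \[0, 90\]. 0 = parallel to the invasive front,
#' 90 = perpendicular.
#'
#' @param fiber_angle,tangent_angle orientations in degrees in \[0, 180)
#'   (vectorized).
#' @return angles in \[0, 90\].
#' @export
relative_angle <- function(fiber_angle, tangent_angle) {
  if (any(fiber_angle < 0 | fiber_angle >= 180, na.rm = TRUE) ||
      any(tangent_angle < 0 | tangent_angle >= 180, na.rm = TRUE))
    stop("orientations must lie in [0, 180)", call. = FALSE)
  d <- abs(fiber_angle - tangent_angle) %% 180
  pmin(d, 180 - d)
}

#' Fiber orientations relative to the tumor invasive front
#'
#' For every pixel that is inside the peritumoral band, carries a valid fiber
#' orientation and (optionally) lies on collagen, the nearest resampled
#' boundary vertex is found (Euclidean distance, ties to the lower vertex
#' index) and the acute angle between each of the pixel's orientations and
#' that vertex's tangent is computed. The display map stores the minimum
#' angle per pixel; all angles enter `samples` individually, so crossing
#' pixels contribute one sample per orientation.
#'
#' @param orients an [orientation_map][compute_orientation_map].
#' @param tangents a [tangent_field][resample_and_tangents].
#' @param band logical H x W band mask ([peritumoral_band()]).
#' @param collagen optional logical H x W collagen mask.
#' @return object of class `relative_orientation_map`: list with `delta`
#'   (H x W matrix of minimum acute angles, NA outside), `multiplicity`
#'   (samples per pixel) and `samples` (all acute angles, degrees).
#' @export
relative_orientation_map <- function(orients, tangents, band, collagen = NULL) {
  stopifnot(inherits(orients, "orientation_map"),
            inherits(tangents, "tangent_field"))
  if (nrow(tangents) == 0) stop("empty tangent field", call. = FALSE)
  if (!all(dim(band) == dim(orients$valid)))
    stop("band and orientation map shapes differ", call. = FALSE)
  sel <- band & orients$valid
  if (!is.null(collagen)) {
    if (!all(dim(collagen) == dim(band)))
      stop("collagen mask shape differs", call. = FALSE)
    sel <- sel & collagen
  }
  h <- nrow(sel); w <- ncol(sel)
  delta <- matrix(NA_real_, h, w)
  mult <- matrix(0L, h, w)
  samples <- numeric(0)
  idx <- which(sel)
  if (length(idx)) {
    px <- (ceiling(idx / h)) - 1          # x = col - 1
    py <- ((idx - 1) %% h)                # y = row - 1
    # nearest tangent vertex, chunked distance computation; which.min takes
    # the first (lowest-index) vertex on ties
    nearest <- integer(length(idx))
    vx <- tangents$x; vy <- tangents$y
    chunk <- 2000L
    for (st in seq(1, length(idx), by = chunk)) {
      en <- min(st + chunk - 1, length(idx))
      D <- outer(px[st:en], vx, `-`)^2 + outer(py[st:en], vy, `-`)^2
      nearest[st:en] <- apply(D, 1, which.min)
    }
    tang <- tangents$tangent_deg[nearest]
    ors <- matrix(orients$orientations, h * w, 3)[idx, , drop = FALSE]
    dels <- matrix(NA_real_, length(idx), 3)
    for (L in 1:3) {
      has <- !is.na(ors[, L])
      if (any(has))
        dels[has, L] <- relative_angle(ors[has, L], tang[has])
    }
    m0 <- rowSums(!is.na(dels))
    dmin <- suppressWarnings(apply(dels, 1, min, na.rm = TRUE))
    dmin[m0 == 0] <- NA_real_
    mult[idx] <- m0
    delta[idx] <- dmin
    samples <- as.numeric(t(dels))
    samples <- samples[!is.na(samples)]
  }
  structure(list(delta = delta, multiplicity = mult, samples = samples),
            class = "relative_orientation_map")
}

#' Colorize a relative orientation map (parallel green, perpendicular magenta)
#'
#' Hue is interpolated linearly along the arc from green (Delta = 0) through
#' cyan and blue to magenta (Delta = 90): hue = 120 + 2 * Delta degrees, full
#' saturation and value. Out-of-band pixels are black.
#'
#' @param relmap a [relative_orientation_map()].
#' @return H x W x 3 integer array, values 0..255.
#' @export
colorize_relative_fom <- function(relmap) {
  stopifnot(inherits(relmap, "relative_orientation_map"))
  d <- relmap$delta
  ok <- !is.na(d)
  out <- matrix(0L, length(d), 3)
  if (any(ok)) {
    hue <- (120 + 2 * d[ok]) / 360
    out[ok, ] <- t(grDevices::col2rgb(grDevices::hsv(hue, 1, 1)))
  }
  array(out, c(nrow(d), ncol(d), 3))
}
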