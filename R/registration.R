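#' Similarity transforms for cross-stain registration
#'
#' A similarity transform maps a point p = (x, y) to `s * R(theta) * p + t`
#' with isotropic scale `s > 0`, rotation `theta` (degrees, anti-clockwise in
#' the (x, y) coordinate frame) and translation `t` — rotation plus isotropic
#' scaling, preserving aspect ratio, with no reflection.
#'
#' @param scale isotropic scale factor (> 0).
#' @param rotation_deg rotation angle in degrees, in (-180, 180].
#' @param tx,ty translation in pixels.
#' @return object of class `similarity_transform`.
#' @export
similarity_transform <- function(scale = 1, rotation_deg = 0, tx = 0, ty = 0) {
  stop_if_not_scalar_number(scale, "scale")
  if (scale <= 0) stop("`scale` must be positive", call. = FALSE)
  rotation_deg <- ((rotation_deg + 180) %% 360) - 180
  if (rotation_deg == -180) rotation_deg <- 180
  structure(list(scale = scale, rotation_deg = rotation_deg,
                 tx = tx, ty = ty),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> s = %.6g, theta = %.6g deg, t = (%.6g, %.6g)\n",
              x$scale, x$rotation_deg, x$tx, x$ty))
  invisible(x)
}

transform_matrix <- function(tf) {
  th <- tf$rotation_deg * pi / 180
  tf$scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Apply a similarity transform to points
#' @param points n x 2 matrix (or length-2 vector) of (x, y) coordinates.
#' @param transform a [similarity_transform()].
#' @return n x 2 matrix of mapped coordinates (exact affine mapping).
#' @export
apply_transform <- function(points, transform) {
  p <- matrix(points, ncol = 2)
  A <- transform_matrix(transform)
  sweep(p %*% t(A), 2, c(transform$tx, transform$ty), `+`)
}

#' Invert a similarity transform
#' @param transform a [similarity_transform()].
#' @return the inverse `similarity_transform`; composing the two is the
#'   identity to within 1e-9.
#' @export
invert_transform <- function(transform) {
  s <- 1 / transform$scale
  th <- -transform$rotation_deg
  A <- transform_matrix(similarity_transform(s, th))
  t2 <- -as.vector(A %*% c(transform$tx, transform$ty))
  similarity_transform(s, th, t2[1], t2[2])
}

#' Estimate a similarity transform from landmark pairs
#'
#' Closed-form least squares (orthogonal Procrustes with isotropic scale,
#' reflection excluded): with centered sources p_i and targets q_i, the
#' rotation is `theta = atan2(sum(p x q), sum(p . q))` and the scale
#' `sqrt((sum p.q)^2 + (sum p x q)^2) / sum |p|^2`; the translation maps the
#' source centroid onto the target centroid. Two distinct points determine
#' the transform exactly; more points give the least-squares fit.
#'
#' @param src,dst n x 2 matrices of (x, y) landmark coordinates (n >= 2), or
#'   a single 4-column data.frame/matrix `(src_x, src_y, dst_x, dst_y)` as
#'   `src` (see [read_landmarks()]).
#' @return a [similarity_transform()] with attribute `rmse`, the
#'   root-mean-square target residual.
#' @export
estimate_similarity <- function(src, dst = NULL) {
  if (is.null(dst)) {
    src <- as.matrix(src)
    stopifnot(ncol(src) == 4)
    dst <- src[, 3:4, drop = FALSE]
    src <- src[, 1:2, drop = FALSE]
  }
  src <- matrix(as.numeric(as.matrix(src)), ncol = 2)
  dst <- matrix(as.numeric(as.matrix(dst)), ncol = 2)
  if (nrow(src) < 2 || nrow(src) != nrow(dst))
    stop("need at least 2 landmark pairs", call. = FALSE)
  sc <- colMeans(src); tc <- colMeans(dst)
  p <- sweep(src, 2, sc); q <- sweep(dst, 2, tc)
  denom <- sum(p^2)
  if (denom == 0)
    stop("source landmarks are coincident: transform underdetermined",
         call. = FALSE)
  Sdot <- sum(p * q)                       # sum of dot products
  Scross <- sum(p[, 1] * q[, 2] - p[, 2] * q[, 1])  # sum of 2D cross products
  theta <- atan2(Scross, Sdot) * 180 / pi
  s <- sqrt(Sdot^2 + Scross^2) / denom
  A <- transform_matrix(similarity_transform(s, theta))
  t2 <- tc - as.vector(A %*% sc)
  tf <- similarity_transform(s, theta, t2[1], t2[2])
  resid <- apply_transform(src, tf) - dst
  attr(tf, "rmse") <- sqrt(mean(rowSums(resid^2)))
  tf
}

#' Warp an image with a similarity transform
#'
#' Inverse-mapping resampling: each output pixel center (in target
#' coordinates) is mapped back through the inverse transform and the source
#' image is interpolated there. Bilinear interpolation by default;
#' nearest-neighbour keeps masks binary. Samples falling outside the source
#' frame take `fill`.
#'
#' @param image numeric matrix (grayscale) in source frame.
#' @param transform the source -> target [similarity_transform()].
#' @param output_shape c(height, width) of the target frame (defaults to the
#'   input shape).
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @param fill value for out-of-frame samples.
#' @return warped matrix of dimension `output_shape`.
#' @export
warp_image <- function(image, transform, output_shape = dim(image),
                       interpolation = c("bilinear", "nearest"), fill = 0) {
  interpolation <- match.arg(interpolation)
  if (any(output_shape < 1)) stop("output shape must be positive", call. = FALSE)
  h <- output_shape[1]; w <- output_shape[2]
  inv <- invert_transform(transform)
  # target pixel centers, 0-based (x = col - 1, y = row - 1)
  gx <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  gy <- matrix(seq_len(h) - 1, h, w)
  sp <- apply_transform(cbind(c(gx), c(gy)), inv)
  xs <- sp[, 1]; ys <- sp[, 2]
  H <- nrow(image); W <- ncol(image)
  out <- rep(fill, h * w)
  if (interpolation == "nearest") {
    r <- round(ys) + 1; c0 <- round(xs) + 1
    ok <- r >= 1 & r <= H & c0 >= 1 & c0 <= W
    out[ok] <- image[cbind(r[ok], c0[ok])]
  } else {
    ok <- xs >= 0 & ys >= 0 & xs <= (W - 1) & ys <= (H - 1)
    # clamp so exact right/bottom border samples interpolate with weight 1
    x0 <- pmin(floor(xs), W - 2); y0 <- pmin(floor(ys), H - 2)
    fx <- xs - x0; fy <- ys - y0
    if (any(ok)) {
      r0 <- y0[ok] + 1; c0 <- x0[ok] + 1
      fxo <- fx[ok]; fyo <- fy[ok]
      v00 <- image[cbind(r0, c0)]
      v01 <- image[cbind(r0, c0 + 1)]
      v10 <- image[cbind(r0 + 1, c0)]
      v11 <- image[cbind(r0 + 1, c0 + 1)]
      out[ok] <- v00 * (1 - fxo) * (1 - fyo) + v01 * fxo * (1 - fyo) +
        v10 * (1 - fxo) * fyo + v11 * fxo * fyo
    }
  }
  matrix(out, h, w)
}

#' Warp a polyline (exact coordinate mapping)
#'
#' @param points n x 2 matrix of (x, y) vertices.
#' @param transform a [similarity_transform()].
#' @return n x 2 matrix; no resampling loss.
#' @export
warp_polyline <- function(points, transform) {
  apply_transform(points, transform)
}
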