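# Shared angle arithmetic and small helpers. All angles in degrees.

#' Reduce angles into [0, 360)
#' @param x numeric vector of angles in degrees.
#' @return angles folded into \[0, 360).
#' @keywords internal
#' @noRd
mod360 <- function(x) x %% 360

#' Reduce orientation angles into [0, 180)
#' @keywords internal
#' @noRd
mod180 <- function(x) x %% 180

# Signed circular difference a - b folded into [-180, 180)
circ_diff <- function(a, b) {
  ((a - b + 180) %% 360) - 180
}

# Circular separation between two azimuths, in [0, 180]
circ_sep <- function(a, b) abs(circ_diff(a, b))

# Circular midpoint of two azimuths: the point halfway along the shorter arc
# from a to b, in [0, 360).
circ_midpoint <- function(a, b) {
  mod360(a + circ_diff(b, a) / 2)
}

#' Orientation angle of a vector in image coordinates
#'
#' Image rows grow downwards, but orientations are measured anti-clockwise on
#' the displayed image, so the y component is negated before `atan2`.
#'
#' @param dx,dy vector components (x along columns, y along rows).
#' @return orientation in degrees in \[0, 180).
#' @keywords internal
#' @noRd
vec_orientation <- function(dx, dy) {
  mod180(atan2(-dy, dx) * 180 / pi)
}

# Evaluate a chunk of code with a temporary RNG seed, restoring the caller's
# RNG state afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  invisible(x)
}

# Ray-casting point-in-polygon test, vectorized over query points.
# poly: n x 2 matrix of (x, y) vertices of a closed polygon (no need to
# repeat the first vertex). Points exactly on an edge may land on either side.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
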