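#' Compute the per-pixel fiber orientation map of an angular stack
#'
#' Runs the full profile -> prominent peaks -> antipodal pairs -> orientations
#' chain ([detect_prominent_peaks()], [pair_antipodal_peaks()],
#' [orientations_from_profile()]) at every pixel. Pixels whose profiles carry
#' 3, 5 or more than 6 peaks, or whose peaks cannot all be paired, are marked
#' invalid; flat (background) profiles have zero peaks and are invalid too.
#'
#' Identical profiles are analysed once and the result broadcast, so noiseless
#' phantoms with piecewise-constant fields cost almost nothing.
#'
#' @param stack an [angular_stack()].
#' @param prominence_threshold minimum normalized peak prominence.
#' @param refine sub-bin parabolic peak refinement (default TRUE).
#' @param tolerance antipodal pairing tolerance in degrees around 180.
#' @return object of class `orientation_map`: list with `orientations`
#'   (H x W x 3 array, degrees in \[0, 180), layer 1 = most prominent pair,
#'   `NA` = absent), `n_orientations`, `peak_count`, `valid` (H x W).
#' @export
compute_orientation_map <- function(stack, prominence_threshold = 0.08,
                                    refine = TRUE, tolerance = 35) {
  stopifnot(inherits(stack, "angular_stack"))
  d <- dim(stack$frames)
  h <- d[1]; w <- d[2]; K <- d[3]
  profs <- matrix(stack$frames, h * w, K)
  ori <- array(NA_real_, c(h, w, 3))
  step <- 360 / K

  # min-max normalize all profiles at once; flat profiles have no peaks
  rmin <- do.call(pmin, lapply(seq_len(K), function(k) profs[, k]))
  rmax <- do.call(pmax, lapply(seq_len(K), function(k) profs[, k]))
  rng <- rmax - rmin
  V <- (profs - rmin) / ifelse(rng == 0, 1, rng)

  grp <- do.call(paste, c(lapply(seq_len(K), function(k) profs[, k]),
                          sep = "\r"))
  first <- !duplicated(grp)
  map_to <- match(grp, grp[first])
  uniq_idx <- which(first)
  res_o <- matrix(NA_real_, length(uniq_idx), 3)
  res_n <- integer(length(uniq_idx))
  res_p <- integer(length(uniq_idx))
  res_v <- logical(length(uniq_idx))
  angles <- stack$angles
  for (u in seq_along(uniq_idx)) {
    i <- uniq_idx[u]
    if (rng[i] == 0) next  # flat: 0 peaks, invalid
    r <- profile_orientations(V[i, ], angles, step, prominence_threshold,
                              refine, tolerance)
    res_p[u] <- r$peak_count
    res_v[u] <- r$valid
    no <- length(r$orientations)
    res_n[u] <- no
    if (no > 0)
      res_o[u, seq_len(min(no, 3))] <- r$orientations[seq_len(min(no, 3))]
  }
  ori[, , 1] <- res_o[map_to, 1]
  ori[, , 2] <- res_o[map_to, 2]
  ori[, , 3] <- res_o[map_to, 3]
  structure(list(orientations = ori,
                 n_orientations = matrix(res_n[map_to], h, w),
                 peak_count = matrix(res_p[map_to], h, w),
                 valid = matrix(res_v[map_to], h, w)),
            class = "orientation_map")
}

#' @export
print.orientation_map <- function(x, ...) {
  cat(sprintf("<orientation_map> %d x %d; valid: %d (%.1f%%)\n",
              nrow(x$valid), ncol(x$valid), sum(x$valid),
              100 * mean(x$valid)))
  invisible(x)
}
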