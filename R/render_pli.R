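#' Render a four-angle polarized light imaging stack
#'
#' A birefringent pixel with retardance delta and fast-axis azimuth phi,
#' measured with linearly polarized ingoing light at polarizer angle rho and a
#' circular analyzer, transmits
#' \deqn{I(\rho) = \frac{I_0}{2}\,[1 + |\sin\delta|\,\sin(2(\rho - \varphi))].}
#' The sign convention (`+sin`) is fixed so that [pli_fit()] applied to a
#' rendered stack returns exactly the input fields (see the package vignette).
#'
#' @param retardance_field matrix of |sin delta| values in \[0, 1\].
#' @param azimuth_field matrix of fast-axis azimuths in \[0, 180) degrees;
#'   ignored (any finite value) where retardance is 0.
#' @param transmittance scalar or matrix I0 >= 0.
#' @param pol_angles polarizer angles in degrees (default c(0, 45, 90, 135)).
#' @return a `pli_stack`: list with `frames` (H x W x 4 array) and
#'   `pol_angles`.
#' @examples
#' s <- render_pli_stack(matrix(1, 1, 1), matrix(30, 1, 1), transmittance = 2)
#' s$frames[1, 1, ]  # 1 + sin(c(-60, 30, 120, 210) * pi / 180)
#' @export
render_pli_stack <- function(retardance_field, azimuth_field,
                             transmittance = 1,
                             pol_angles = c(0, 45, 90, 135)) {
  retardance_field <- as.matrix(retardance_field)
  azimuth_field <- as.matrix(azimuth_field)
  if (!all(dim(retardance_field) == dim(azimuth_field)))
    stop("retardance and azimuth fields must share dimensions", call. = FALSE)
  if (any(retardance_field < 0 | retardance_field > 1, na.rm = TRUE))
    stop("|sin delta| values must lie in [0, 1]", call. = FALSE)
  if (any(transmittance < 0)) stop("transmittance must be >= 0", call. = FALSE)
  h <- nrow(retardance_field); w <- ncol(retardance_field)
  I0 <- if (length(transmittance) == 1) matrix(transmittance, h, w)
        else as.matrix(transmittance)
  frames <- array(NA_real_, c(h, w, length(pol_angles)))
  for (k in seq_along(pol_angles)) {
    rho <- pol_angles[k]
    frames[, , k] <- (I0 / 2) *
      (1 + retardance_field * sin(2 * (rho - azimuth_field) * pi / 180))
  }
  structure(list(frames = frames, pol_angles = pol_angles),
            class = "pli_stack")
}
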