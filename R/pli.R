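#' Fit the polarized light imaging sinusoid per pixel
#'
#' With frames I0, I45, I90, I135 acquired at polarizer angles 0, 45, 90 and
#' 135 degrees, the discrete Fourier coefficients of the two-cycle sinusoid
#' are recovered exactly from the four samples:
#' \deqn{a_0 = (I_0 + I_{45} + I_{90} + I_{135})/4,\quad
#'       a = (I_0 - I_{90})/2,\quad b = (I_{45} - I_{135})/2.}
#' The retardance is the relative modulation amplitude
#' `|sin delta| = sqrt(a^2 + b^2) / a0`, and the fast-axis azimuth is half the
#' phase, `phi = atan2(-a, b) / 2` reduced into \[0, 180) — the sign
#' convention matching [render_pli_stack()]'s `I(rho) = (I0/2) [1 +
#' |sin delta| sin(2 (rho - phi))]`, so render -> fit is the identity.
#' Pixels with `a0 = 0` or retardance below `epsilon` have an undefined
#' azimuth (NA).
#'
#' @param stack a `pli_stack` (see [render_pli_stack()]) or an H x W x 4
#'   array ordered by polarizer angle 0, 45, 90, 135.
#' @param epsilon retardance below which the azimuth is flagged undefined.
#' @return object of class `pli_result`: list with matrices `retardance`
#'   (|sin delta| in \[0, 1\]), `azimuth` (degrees in \[0, 180), NA where
#'   undefined), `transmittance` (a0) and `defined` (logical).
#' @examples
#' s <- render_pli_stack(matrix(1, 1, 1), matrix(30, 1, 1), transmittance = 2)
#' fit <- pli_fit(s)
#' c(fit$retardance, fit$azimuth)  # 1, 30
#' @export
pli_fit <- function(stack, epsilon = 1e-3) {
  frames <- if (inherits(stack, "pli_stack")) stack$frames else stack
  if (length(dim(frames)) != 3 || dim(frames)[3] != 4)
    stop("a PLI stack must hold exactly 4 frames", call. = FALSE)
  h <- dim(frames)[1]; w <- dim(frames)[2]
  pg <- function(k) matrix(frames[, , k], h, w)
  I0 <- pg(1); I45 <- pg(2); I90 <- pg(3); I135 <- pg(4)
  a0 <- (I0 + I45 + I90 + I135) / 4
  a <- (I0 - I90) / 2
  b <- (I45 - I135) / 2
  amp <- sqrt(a^2 + b^2)
  ret <- ifelse(a0 > 0, amp / a0, NA_real_)
  az <- mod180(atan2(-a, b) * 180 / pi / 2)
  defined <- !is.na(ret) & ret >= epsilon
  az[!defined] <- NA_real_
  structure(list(retardance = ret, azimuth = az, transmittance = a0,
                 defined = defined),
            class = "pli_result")
}

#' Colorize a PLI result with the fiber-orientation color wheel
#'
#' Uses the same hue wheel as [colorize_fom()] (red = 0 degrees, cyan = 90);
#' undefined pixels are black. Optionally the color value (brightness) is
#' weighted by the retardance.
#'
#' @param result a [pli_result][pli_fit].
#' @param value_weight logical; scale brightness by retardance.
#' @return H x W x 3 integer array, values 0..255.
#' @export
colorize_pli <- function(result, value_weight = FALSE) {
  stopifnot(inherits(result, "pli_result"))
  theta <- result$azimuth
  h <- nrow(theta); w <- ncol(theta)
  rgb <- orientation_to_rgb(c(theta))
  if (value_weight) {
    v <- c(result$retardance)
    v[is.na(v)] <- 0
    rgb <- matrix(as.integer(round(rgb * v)), nrow(rgb), 3)
  }
  array(rgb, c(h, w, 3))
}
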