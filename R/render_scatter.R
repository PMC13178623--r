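#' Forward model for azimuthal scattering profiles
#'
#' A fiber oriented at theta scatters obliquely incident light mainly
#' perpendicular to its axis, producing a pair of antipodal peaks in the
#' azimuthal intensity profile I(phi) at theta + 90 and theta + 270 degrees.
#' The renderer models each peak as a wrapped Gaussian of standard deviation
#' `peak_width_sigma` and unit peak height scaled by the fiber amplitude, on
#' top of a constant baseline.
#'
#' @param step azimuthal step in degrees; the grid is `seq(0, 360 - step,
#'   step)` covering a full circle (default 15, i.e. K = 24 frames).
#' @param baseline constant intensity offset (>= 0).
#' @param peak_amplitude intensity scale of a unit-amplitude fiber peak.
#' @param peak_width_sigma wrapped-Gaussian standard deviation in degrees.
#' @param noise_sigma per-single-exposure additive Gaussian noise sd; each
#'   stored frame is the average of `frames_averaged` exposures, so the
#'   applied sd is `noise_sigma / sqrt(frames_averaged)`.
#' @param frames_averaged exposures averaged per stored frame (default 4).
#' @return object of class `scatter_model`.
#' @examples
#' m <- scatter_model()
#' length(m$angles)  # 24
#' @export
scatter_model <- function(step = 15, baseline = 0.1, peak_amplitude = 1,
                          peak_width_sigma = 20, noise_sigma = 0.02,
                          frames_averaged = 4) {
  stop_if_not_scalar_number(step, "step")
  if (step <= 0 || 360 %% step != 0)
    stop("`step` must divide 360", call. = FALSE)
  if (360 / step < 8) stop("need at least 8 azimuthal angles", call. = FALSE)
  if (baseline < 0 || peak_amplitude < 0 || noise_sigma < 0)
    stop("intensity parameters must be non-negative", call. = FALSE)
  if (peak_width_sigma <= 0)
    stop("`peak_width_sigma` must be positive", call. = FALSE)
  structure(list(step = step, angles = seq(0, 360 - step, by = step),
                 baseline = baseline, peak_amplitude = peak_amplitude,
                 peak_width_sigma = peak_width_sigma,
                 noise_sigma = noise_sigma,
                 frames_averaged = frames_averaged),
            class = "scatter_model")
}

# Wrapped Gaussian kernel with unit peak height: sum of Gaussians at
# x + 360 k. x is folded to [-180, 180) first, so one flank either side
# suffices for sigma <= 60.
wrapped_gaussian <- function(x, sigma) {
  d <- ((x + 180) %% 360) - 180
  exp(-d^2 / (2 * sigma^2)) +
    exp(-(d - 360)^2 / (2 * sigma^2)) +
    exp(-(d + 360)^2 / (2 * sigma^2))
}

#' Closed-form noiseless scattering profile of one pixel
#'
#' @param phi azimuth angles (degrees) at which to evaluate.
#' @param thetas fiber orientations in \[0, 180).
#' @param amplitudes per-fiber amplitudes (recycled).
#' @param model a [scatter_model()].
#' @return intensities at `phi`.
#' @export
scatter_profile <- function(phi, thetas, amplitudes = 1, model = scatter_model()) {
  amplitudes <- rep_len(amplitudes, length(thetas))
  out <- rep(model$baseline, length(phi))
  for (i in seq_along(thetas)) {
    out <- out + model$peak_amplitude * amplitudes[i] *
      (wrapped_gaussian(phi - (thetas[i] + 90), model$peak_width_sigma) +
       wrapped_gaussian(phi - (thetas[i] + 270), model$peak_width_sigma))
  }
  out
}

#' Render an orientation field into an angular scattering stack
#'
#' Every pixel's noiseless profile is `baseline + sum over fibers of
#' amplitude * [W(phi; theta + 90, sigma) + W(phi; theta + 270, sigma)]`
#' with W a wrapped Gaussian; background pixels render as baseline only.
#' Independent Gaussian noise of sd `noise_sigma / sqrt(frames_averaged)` is
#' added to every frame. Rendering is deterministic given `seed`.
#'
#' @param field an [orientation_field][make_orientation_field].
#' @param model a [scatter_model()].
#' @param seed integer seed for the noise; `NULL` uses (and advances) the
#'   current RNG state.
#' @return an [angular_stack()] of dimension H x W x K.
#' @export
render_scatter_stack <- function(field, model = scatter_model(), seed = NULL) {
  stopifnot(inherits(field, "orientation_field"),
            inherits(model, "scatter_model"))
  h <- field$height; w <- field$width
  K <- length(model$angles)
  frames <- array(model$baseline, c(h, w, K))
  for (layer in 1:2) {
    th <- field$orientations[, , layer]
    sel <- !is.na(th)
    if (!any(sel)) next
    am <- field$amplitudes[, , layer]
    am[is.na(am)] <- 0
    for (k in seq_len(K)) {
      contrib <- model$peak_amplitude * am[sel] *
        (wrapped_gaussian(model$angles[k] - (th[sel] + 90),
                          model$peak_width_sigma) +
         wrapped_gaussian(model$angles[k] - (th[sel] + 270),
                          model$peak_width_sigma))
      fr <- frames[, , k]
      fr[sel] <- fr[sel] + contrib
      frames[, , k] <- fr
    }
  }
  if (model$noise_sigma > 0) {
    sd_eff <- model$noise_sigma / sqrt(model$frames_averaged)
    noise <- with_seed(seed, stats::rnorm(length(frames), sd = sd_eff))
    frames <- frames + array(noise, dim(frames))
  }
  angular_stack(frames, model$angles)
}
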