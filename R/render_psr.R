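#' Render a synthetic picrosirius-red bright-field image
#'
#' Collagen appears red under PSR staining, so collagen pixels are drawn with
#' high red and low green channel values (green well below the 205 masking
#' threshold), background as white, and optional non-collagen tissue in a pale
#' pink with a high green channel. Mild Gaussian pixel noise emulates scanner
#' texture; the noise never carries a pixel across the green-channel masking
#' band.
#'
#' @param collagen_truth logical matrix, `TRUE` = collagen.
#' @param tissue_truth optional logical matrix of non-collagen tissue.
#' @param seed integer seed for the pixel noise.
#' @param noise_sd sd of the additive channel noise (8-bit counts).
#' @return 8-bit RGB image as an H x W x 3 integer array with values 0..255.
#' @export
render_psr_image <- function(collagen_truth, tissue_truth = NULL, seed = NULL,
                             noise_sd = 4) {
  collagen_truth <- as.matrix(collagen_truth)
  h <- nrow(collagen_truth); w <- ncol(collagen_truth)
  r <- matrix(255, h, w); g <- matrix(255, h, w); b <- matrix(255, h, w)
  if (!is.null(tissue_truth)) {
    tt <- as.matrix(tissue_truth) & !collagen_truth
    r[tt] <- 245; g[tt] <- 225; b[tt] <- 230   # pale pink, green >= 205
  }
  r[collagen_truth] <- 200
  g[collagen_truth] <- 60                       # far below the 205 threshold
  b[collagen_truth] <- 70
  fg <- collagen_truth
  if (!is.null(tissue_truth)) fg <- fg | as.matrix(tissue_truth)
  if (noise_sd > 0 && any(fg)) {
    # noise textures stained tissue only; the white background stays exact
    n <- with_seed(seed, stats::rnorm(3 * sum(fg), sd = noise_sd))
    m <- sum(fg)
    r[fg] <- r[fg] + n[seq_len(m)]
    g[fg] <- g[fg] + n[m + seq_len(m)]
    b[fg] <- b[fg] + n[2 * m + seq_len(m)]
    # keep tissue green inside [205,255] and collagen well outside
    g[collagen_truth] <- pmin(g[collagen_truth], 200)
    g[fg & !collagen_truth] <- pmax(pmin(g[fg & !collagen_truth], 255), 208)
  }
  clip8 <- function(m) matrix(as.integer(pmax(0, pmin(255, round(m)))),
                              nrow(m), ncol(m))
  out <- array(0L, c(h, w, 3))
  out[, , 1] <- clip8(r); out[, , 2] <- clip8(g); out[, , 3] <- clip8(b)
  out
}
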