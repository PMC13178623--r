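#' Collagen mask from a picrosirius-red bright-field RGB image
#'
#' Collagen appears red after PSR staining, so its green-channel values are
#' low while the white background (and pale counterstained tissue) has green
#' values in the high band \[205, 255\]. The mask selects pixels whose chosen
#' channel value lies inside `[lo, hi]` when `select_inside = TRUE`, or its
#' complement otherwise. The default — green channel, band \[205, 255\],
#' `select_inside = FALSE` — marks as collagen every pixel whose green value
#' falls below 205 (both polarities are supported because thresholding the
#' high-green band can equally be read as selecting background to invert).
#'
#' @param rgb 8-bit RGB image: H x W x 3 array with values 0..255 (or 0..1,
#'   rescaled automatically).
#' @param channel `"red"`, `"green"` (default) or `"blue"`.
#' @param lo,hi inclusive channel band, 0..255 (defaults 205, 255).
#' @param select_inside if `TRUE`, pixels inside the band are collagen; if
#'   `FALSE` (default) the complement is.
#' @return logical H x W matrix, `TRUE` = collagen.
#' @export
collagen_mask_from_rgb <- function(rgb, channel = c("green", "red", "blue"),
                                   lo = 205, hi = 255, select_inside = FALSE) {
  channel <- match.arg(channel)
  if (length(dim(rgb)) != 3 || dim(rgb)[3] < 3)
    stop("`rgb` must be an H x W x 3 array", call. = FALSE)
  if (lo > hi) stop("`lo` must not exceed `hi`", call. = FALSE)
  ch <- matrix(rgb[, , match(channel, c("red", "green", "blue"))],
               dim(rgb)[1], dim(rgb)[2])
  if (max(ch) <= 1) ch <- ch * 255  # images read by png come scaled to [0,1]
  inside <- ch >= lo & ch <= hi
  if (select_inside) inside else !inside
}

#' Dice similarity coefficient between two binary masks
#'
#' `2 |A & B| / (|A| + |B|)`; 1 for identical non-empty masks. Defined as 1
#' when both masks are empty.
#'
#' @param a,b logical matrices of equal shape.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
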