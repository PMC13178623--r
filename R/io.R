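# Artifact interchange. Float maps go to 32-bit float multi-page TIFF with a
# JSON sidecar; 8-bit imagery to PNG; geometry, transforms and landmarks to
# JSON/CSV. Writing then reading preserves values exactly (float maps at
# single precision, NaN positions included); sidecar/metadata mismatches are
# refused with the offending field named.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop(sprintf("missing sidecar `%s`", sp), call. = FALSE)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write / read an angular scattering stack
#'
#' The stack is stored as a multi-page 32-bit float TIFF (one page per
#' illumination angle) with a JSON sidecar holding `angles_deg`,
#' `pixel_size_um` and optionally `seed` and `provenance`. Loading refuses a
#' sidecar whose angle count does not match the stored frames.
#'
#' @param stack an [angular_stack()].
#' @param path output `.tif` path (sidecar written next to it).
#' @param seed,provenance optional metadata recorded in the sidecar.
#' @return `path`, invisibly; for the reader, an [angular_stack()].
#' @export
write_angular_stack <- function(stack, path, seed = NULL, provenance = NULL) {
  stopifnot(inherits(stack, "angular_stack"))
  K <- dim(stack$frames)[3]
  write_float_tiff(lapply(seq_len(K), function(k) stack$frames[, , k]), path)
  write_sidecar(path, list(angles_deg = stack$angles,
                           pixel_size_um = stack$pixel_size,
                           seed = seed, provenance = provenance))
  invisible(path)
}

#' @rdname write_angular_stack
#' @export
read_angular_stack <- function(path) {
  meta <- read_sidecar(path)
  pages <- read_float_tiff(path)
  if (is.null(meta$angles_deg))
    stop("sidecar field `angles_deg` is missing", call. = FALSE)
  if (length(meta$angles_deg) != length(pages))
    stop(sprintf(
      "sidecar field `angles_deg` has %d entries but the stack has %d frames",
      length(meta$angles_deg), length(pages)), call. = FALSE)
  frames <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  angular_stack(frames, meta$angles_deg,
                pixel_size = meta$pixel_size_um)
}

#' Write / read an orientation map
#'
#' Orientations are stored as a 3-page 32-bit float TIFF (one page per
#' orientation layer, NaN = absent) plus a page holding the per-pixel peak
#' count, with a sidecar recording the layer layout.
#'
#' @param orients an [orientation_map][compute_orientation_map].
#' @param path output `.tif` path.
#' @return `path` invisibly; the reader returns an `orientation_map`.
#' @export
write_orientation_map <- function(orients, path) {
  stopifnot(inherits(orients, "orientation_map"))
  pages <- lapply(1:3, function(L) {
    m <- orients$orientations[, , L]
    m[is.na(m)] <- NaN
    m
  })
  pages[[4]] <- matrix(as.numeric(orients$peak_count),
                       nrow(orients$valid), ncol(orients$valid))
  write_float_tiff(pages, path)
  write_sidecar(path, list(layers = c("orientation_1", "orientation_2",
                                      "orientation_3", "peak_count"),
                           angles_unit = "degrees"))
  invisible(path)
}

#' @rdname write_orientation_map
#' @export
read_orientation_map <- function(path) {
  pages <- read_float_tiff(path)
  if (length(pages) != 4)
    stop("orientation map file must hold 4 pages", call. = FALSE)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  ori <- array(NA_real_, c(h, w, 3))
  for (L in 1:3) {
    m <- pages[[L]]
    m[is.nan(m)] <- NA_real_
    ori[, , L] <- m
  }
  n_or <- matrix(rowSums(cbind(c(!is.na(ori[, , 1])), c(!is.na(ori[, , 2])),
                               c(!is.na(ori[, , 3])))), h, w)
  structure(list(orientations = ori, n_orientations = n_or,
                 peak_count = matrix(as.integer(round(pages[[4]])), h, w),
                 valid = n_or > 0),
            class = "orientation_map")
}

#' Write / read a single float map (average intensity, retardance, ...)
#' @param map numeric matrix (NA stored as NaN).
#' @param path output `.tif` path.
#' @export
write_float_map <- function(map, path) {
  m <- as.matrix(map)
  m[is.na(m)] <- NaN
  write_float_tiff(m, path)
  invisible(path)
}

#' @rdname write_float_map
#' @export
read_float_map <- function(path) {
  m <- read_float_tiff(path)[[1]]
  m[is.nan(m)] <- NA_real_
  m
}

#' Write / read a binary mask as 8-bit PNG (0/255)
#' @param mask logical matrix.
#' @param path output `.png` path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  png::readPNG(path) >= 0.5
}

#' Write / read an 8-bit RGB image as PNG
#' @param rgb H x W x 3 array with values 0..255.
#' @param path output `.png` path.
#' @export
write_rgb_image <- function(rgb, path) {
  png::writePNG(rgb / 255, path)
  invisible(path)
}

#' @rdname write_rgb_image
#' @export
read_rgb_image <- function(path) {
  img <- png::readPNG(path)
  array(as.integer(round(img * 255)), dim(img))
}

#' Write / read a boundary annotation as JSON
#'
#' Format: `{"curves": [{"closed": true, "points": [[x, y], ...]}, ...]}`;
#' vertex order is preserved exactly.
#'
#' @param boundary a [boundary_annotation()].
#' @param path output `.json` path.
#' @export
write_boundary <- function(boundary, path) {
  if (!inherits(boundary, "boundary_annotation"))
    boundary <- boundary_annotation(boundary)
  curves <- lapply(boundary$curves, function(cv) {
    list(closed = cv$closed,
         points = lapply(seq_len(nrow(cv$points)),
                         function(i) as.numeric(cv$points[i, ])))
  })
  jsonlite::write_json(list(curves = curves), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_boundary
#' @export
read_boundary <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$curves))
    stop("boundary JSON field `curves` is missing", call. = FALSE)
  curves <- lapply(raw$curves, function(cv) {
    pts <- do.call(rbind, lapply(cv$points, function(p) as.numeric(unlist(p))))
    list(points = pts, closed = isTRUE(cv$closed))
  })
  boundary_annotation(curves)
}

#' Write / read landmark pairs as CSV
#'
#' Four columns with header `src_x, src_y, dst_x, dst_y`.
#'
#' @param landmarks data.frame or matrix with those four columns.
#' @param path output `.csv` path.
#' @export
write_landmarks <- function(landmarks, path) {
  lm <- as.data.frame(landmarks)
  names(lm) <- c("src_x", "src_y", "dst_x", "dst_y")
  utils::write.csv(lm, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  lm <- utils::read.csv(path)
  need <- c("src_x", "src_y", "dst_x", "dst_y")
  if (!all(need %in% names(lm)))
    stop(sprintf("landmark CSV must have header columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  lm[need]
}

#' Write / read a similarity transform as JSON
#'
#' Format: `{"scale": s, "rotation_deg": theta, "tx": ..., "ty": ...}`,
#' numerics at full precision.
#'
#' @param transform a [similarity_transform()].
#' @param path output `.json` path.
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "similarity_transform"))
  jsonlite::write_json(unclass(transform)[c("scale", "rotation_deg",
                                            "tx", "ty")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("scale", "rotation_deg", "tx", "ty"))
    if (is.null(x[[f]]))
      stop(sprintf("transform JSON field `%s` is missing", f), call. = FALSE)
  similarity_transform(x$scale, x$rotation_deg, x$tx, x$ty)
}

#' Write / read a PLI stack (4-page float TIFF + sidecar with pol_angles)
#' @param stack a `pli_stack` from [render_pli_stack()].
#' @param path output `.tif` path.
#' @export
write_pli_stack <- function(stack, path) {
  stopifnot(inherits(stack, "pli_stack"))
  write_float_tiff(lapply(1:4, function(k) stack$frames[, , k]), path)
  write_sidecar(path, list(pol_angles_deg = stack$pol_angles))
  invisible(path)
}

#' @rdname write_pli_stack
#' @export
read_pli_stack <- function(path) {
  meta <- read_sidecar(path)
  pages <- read_float_tiff(path)
  if (is.null(meta$pol_angles_deg))
    stop("sidecar field `pol_angles_deg` is missing", call. = FALSE)
  if (length(pages) != length(meta$pol_angles_deg))
    stop(sprintf(
      "sidecar field `pol_angles_deg` has %d entries but the stack has %d frames",
      length(meta$pol_angles_deg), length(pages)), call. = FALSE)
  frames <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  structure(list(frames = frames, pol_angles = meta$pol_angles_deg),
            class = "pli_stack")
}
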