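# Minimal multi-page 32-bit float TIFF writer.
#
# The tiff package reads IEEE-float TIFFs (including NaN) but only writes
# integer sample formats, so float maps are written here directly:
# uncompressed, little-endian, one strip per page, SampleFormat = IEEE float.
# Everything written by this function reads back bit-exactly (at single
# precision) through tiff::readTIFF.

TIFF_TYPE_SHORT <- 3L
TIFF_TYPE_LONG <- 4L

write_float_tiff <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1, all(vapply(pages, is.matrix, logical(1))))
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header: II, magic 42, offset of first IFD (patched later)
  writeBin(charToRaw("II"), con)
  wr2(42L)
  n <- length(pages)
  # layout: header (8) | page data ... | IFDs
  data_off <- integer(n)
  off <- 8L
  for (i in seq_len(n)) {
    data_off[i] <- off
    off <- off + 4L * length(pages[[i]])
  }
  ifd_off <- integer(n)
  ifd_size <- 2L + 9L * 12L + 4L  # entry count + 9 entries + next-IFD pointer
  for (i in seq_len(n)) ifd_off[i] <- off + (i - 1L) * ifd_size
  wr4(ifd_off[1])
  for (p in pages) {
    # row-major pixel order; writeBin size=4 stores IEEE single (NaN kept)
    writeBin(as.numeric(t(p)), con, size = 4, endian = "little")
  }
  entry <- function(tag, type, count, value) {
    wr2(tag); wr2(type); wr4(count)
    if (type == TIFF_TYPE_SHORT && count == 1) { wr2(value); wr2(0L) }
    else wr4(value)
  }
  for (i in seq_len(n)) {
    h <- nrow(pages[[i]]); w <- ncol(pages[[i]])
    wr2(9L)
    entry(256L, TIFF_TYPE_LONG, 1L, w)              # ImageWidth
    entry(257L, TIFF_TYPE_LONG, 1L, h)              # ImageLength
    entry(258L, TIFF_TYPE_SHORT, 1L, 32L)           # BitsPerSample
    entry(259L, TIFF_TYPE_SHORT, 1L, 1L)            # Compression: none
    entry(262L, TIFF_TYPE_SHORT, 1L, 1L)            # Photometric: min-is-black
    entry(273L, TIFF_TYPE_LONG, 1L, data_off[i])    # StripOffsets
    entry(278L, TIFF_TYPE_LONG, 1L, h)              # RowsPerStrip
    entry(279L, TIFF_TYPE_LONG, 1L, 4L * h * w)     # StripByteCounts
    entry(339L, TIFF_TYPE_SHORT, 1L, 3L)            # SampleFormat: IEEE float
    wr4(if (i < n) ifd_off[i + 1] else 0L)
  }
  invisible(path)
}

read_float_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages
}
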