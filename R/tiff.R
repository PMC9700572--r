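# Minimal baseline TIFF codec (uncompressed grayscale, 8- or 16-bit, single
# sample). Written against the TIFF 6.0 baseline because no TIFF package is
# available in the target library; covers exactly what the exporter emits.

TAG_WIDTH <- 256L
TAG_LENGTH <- 257L
TAG_BITS <- 258L
TAG_COMPRESSION <- 259L
TAG_PHOTOMETRIC <- 262L
TAG_STRIP_OFFSETS <- 273L
TAG_SAMPLES_PER_PIXEL <- 277L
TAG_ROWS_PER_STRIP <- 278L
TAG_STRIP_BYTE_COUNTS <- 279L
TAG_SAMPLE_FORMAT <- 339L

#' Write a grayscale matrix as an uncompressed 16-bit TIFF
#'
#' Row-major, little-endian, single strip. Intensities are rounded and
#' clamped to the representable range 0..65535.
#'
#' @param pixels numeric matrix, rows are image rows (y down).
#' @param path output file path.
#' @export
write_tiff_gray16 <- function(pixels, path) {
  stopifnot(is.matrix(pixels))
  h <- nrow(pixels)
  w <- ncol(pixels)
  v <- as.integer(pmin(pmax(round(pixels), 0), 65535))
  data <- as.vector(t(matrix(v, h, w)))  # row-major scanlines
  nbytes <- length(data) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L + nbytes, con, size = 4, endian = "little")  # IFD after data
  writeBin(data, con, size = 2, endian = "little")
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) { # SHORT: value in the low 2 bytes of the 4-byte field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  writeBin(10L, con, size = 2, endian = "little")  # number of IFD entries
  entry(TAG_WIDTH, 4L, 1L, w)
  entry(TAG_LENGTH, 4L, 1L, h)
  entry(TAG_BITS, 3L, 1L, 16L)
  entry(TAG_COMPRESSION, 3L, 1L, 1L)
  entry(TAG_PHOTOMETRIC, 3L, 1L, 1L)      # BlackIsZero
  entry(TAG_STRIP_OFFSETS, 4L, 1L, 8L)
  entry(TAG_SAMPLES_PER_PIXEL, 3L, 1L, 1L)
  entry(TAG_ROWS_PER_STRIP, 4L, 1L, h)
  entry(TAG_STRIP_BYTE_COUNTS, 4L, 1L, nbytes)
  entry(TAG_SAMPLE_FORMAT, 3L, 1L, 1L)    # unsigned integer
  writeBin(0L, con, size = 4, endian = "little")  # no further IFD
  invisible(path)
}

#' Read an uncompressed grayscale TIFF into a matrix
#'
#' Supports baseline uncompressed 8- or 16-bit single-sample images in either
#' byte order, possibly split into multiple strips.
#'
#' @param path TIFF file path.
#' @return Numeric matrix of intensities, rows are image rows.
#' @export
read_tiff_gray <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8) abort_afd("not a TIFF file (truncated)", "io_error")
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
            else abort_afd("not a TIFF file (bad byte order mark)", "io_error")
  rd <- function(off, size, n = 1L, signed = TRUE) {
    if (size == 4L) signed <- TRUE  # readBin restriction; offsets stay < 2^31
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = signed)
  }
  if (rd(2, 2, signed = FALSE) != 42L) {
    abort_afd("not a TIFF file (bad magic)", "io_error")
  }
  ifd <- rd(4, 4)
  n_entries <- rd(ifd, 2, signed = FALSE)
  tags <- list()
  for (i in seq_len(n_entries)) {
    off <- ifd + 2 + (i - 1) * 12
    tag <- rd(off, 2, signed = FALSE)
    type <- rd(off + 2, 2, signed = FALSE)
    count <- rd(off + 4, 4)
    size <- c(1L, 1L, 2L, 4L)[min(type, 4L)]
    vals <- if (count * size <= 4) {
      rd(off + 8, size, count, signed = FALSE)
    } else {
      rd(rd(off + 8, 4), size, count, signed = FALSE)
    }
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) abort_afd(sprintf("TIFF tag %d missing", tag),
                                      "io_error")
      default
    } else v
  }
  w <- need(TAG_WIDTH)
  h <- need(TAG_LENGTH)
  bits <- need(TAG_BITS, 1L)
  if (need(TAG_COMPRESSION, 1L) != 1L) {
    abort_afd("only uncompressed TIFF is supported", "io_error")
  }
  if (need(TAG_SAMPLES_PER_PIXEL, 1L) != 1L) {
    abort_afd("only single-sample grayscale TIFF is supported", "io_error")
  }
  if (!bits %in% c(8L, 16L)) {
    abort_afd("only 8- or 16-bit TIFF is supported", "io_error")
  }
  offsets <- need(TAG_STRIP_OFFSETS)
  counts <- need(TAG_STRIP_BYTE_COUNTS)
  bpp <- bits %/% 8L
  px <- unlist(lapply(seq_along(offsets), function(i) {
    rd(offsets[i], bpp, counts[i] %/% bpp, signed = FALSE)
  }), use.names = FALSE)
  if (length(px) < w * h) abort_afd("TIFF pixel data truncated", "io_error")
  matrix(px[seq_len(w * h)], nrow = h, ncol = w, byrow = TRUE)
}
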