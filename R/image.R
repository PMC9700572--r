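#' Calibrated cross-sectional image
#'
#' A 2D intensity grid on an HU-like scale with a physical pixel size and
#' plane/phase/subject metadata. Coordinate convention: origin at the center
#' of the top-left pixel, x rightward (columns), y downward (rows); physical
#' coordinates are zero-based pixel indices times `mm_per_pixel`.
#'
#' @param pixels numeric matrix of intensities (rows = y, cols = x).
#' @param mm_per_pixel physical pixel size in mm, positive.
#' @param plane `"annulus"` or `"lvot"`.
#' @param phase `"systole"` or `"diastole"`.
#' @param subject_id opaque identifier.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, mm_per_pixel, plane = "annulus",
                             phase = "diastole", subject_id = NA_character_) {
  if (!is.matrix(pixels) || nrow(pixels) < 1 || ncol(pixels) < 1) {
    abort_afd("pixels must be a non-empty matrix", "invalid_parameter")
  }
  if (!is.numeric(mm_per_pixel) || length(mm_per_pixel) != 1 ||
      !is.finite(mm_per_pixel) || mm_per_pixel <= 0) {
    abort_afd("mm_per_pixel must be a positive number", "invalid_parameter")
  }
  plane <- match.arg(plane, c("annulus", "lvot"))
  phase <- match.arg(phase, c("systole", "diastole"))
  structure(list(pixels = pixels, mm_per_pixel = mm_per_pixel, plane = plane,
                 phase = phase, subject_id = subject_id),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %dx%d px @ %.4g mm/px, %s/%s, subject %s\n",
              nrow(x$pixels), ncol(x$pixels), x$mm_per_pixel, x$plane,
              x$phase, x$subject_id))
  invisible(x)
}

# physical center of the image in mm
image_center_mm <- function(image) {
  c((ncol(image$pixels) - 1) / 2, (nrow(image$pixels) - 1) / 2) *
    image$mm_per_pixel
}

#' Write a calibrated image to a 16-bit grayscale TIFF
#' @param image a [calibrated_image()].
#' @param path output path.
#' @export
write_calibrated_image <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  write_tiff_gray16(image$pixels, path)
}

#' Read a grayscale TIFF into a calibrated image
#'
#' The TIFF itself carries no physical scale; pass `mm_per_pixel` explicitly
#' or leave it `NA` and recover it later with [calibrate_from_compass()].
#'
#' @param path TIFF path.
#' @param mm_per_pixel physical scale, or `NA` if it must be recovered from
#'   the compass ring.
#' @inheritParams calibrated_image
#' @export
read_calibrated_image <- function(path, mm_per_pixel = NA_real_,
                                  plane = "annulus", phase = "diastole",
                                  subject_id = NA_character_) {
  px <- read_tiff_gray(path)
  img <- structure(list(pixels = px, mm_per_pixel = mm_per_pixel,
                        plane = match.arg(plane, c("annulus", "lvot")),
                        phase = match.arg(phase, c("systole", "diastole")),
                        subject_id = subject_id),
                   class = "calibrated_image")
  img
}
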