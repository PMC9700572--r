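#' Rendering parameters for a synthetic CT slice
#'
#' Intensities live on an HU-like unsigned 16-bit scale. The default lumen
#' intensity of 400 sits above the 300-HU suitability gate; contrast-poor
#' images for gate tests are produced by lowering it. Calcium foci are bright
#' disks clipped against the lumen so they indent the detected border; the
#' compass ring is a 1-px near-maximal-intensity circle of known physical
#' diameter used for pixel-to-mm calibration.
#'
#' @param mm_per_pixel physical pixel size, mm.
#' @param image_size_px integer `c(rows, cols)`.
#' @param lumen_intensity,tissue_intensity HU-like values;
#'   `lumen_intensity > tissue_intensity` is required.
#' @param noise_sd additive Gaussian noise SD (HU-like), truncated to the
#'   16-bit range after addition.
#' @param calcium_foci list of `list(center = c(x_mm, y_mm), radius_mm,
#'   intensity)`.
#' @param compass_diameter_mm physical diameter of the calibration ring, or
#'   `NULL` for no ring.
#' @param compass_intensity intensity of the ring (near the top of the scale).
#' @param anti_alias if `TRUE` (default), border pixels get partial-volume
#'   intensities (4x4 supersampled area coverage), emulating how CT voxels
#'   average tissue fractions; `FALSE` gives hard point-sampled pixels.
#' @param seed integer seed for the noise field.
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(mm_per_pixel = 0.1, image_size_px = c(512, 512),
                        lumen_intensity = 400, tissue_intensity = 50,
                        noise_sd = 0, calcium_foci = list(),
                        compass_diameter_mm = NULL,
                        compass_intensity = 32000, anti_alias = TRUE,
                        seed = 1) {
  if (mm_per_pixel <= 0) {
    abort_afd("mm_per_pixel must be positive", "invalid_parameter")
  }
  if (lumen_intensity <= tissue_intensity) {
    abort_afd("lumen_intensity must exceed tissue_intensity",
              "invalid_parameter")
  }
  if (noise_sd < 0) abort_afd("noise_sd must be >= 0", "invalid_parameter")
  if (!is.null(compass_diameter_mm) && compass_diameter_mm <= 0) {
    abort_afd("compass_diameter_mm must be positive", "invalid_parameter")
  }
  structure(list(mm_per_pixel = mm_per_pixel,
                 image_size_px = as.integer(image_size_px),
                 lumen_intensity = lumen_intensity,
                 tissue_intensity = tissue_intensity,
                 noise_sd = noise_sd, calcium_foci = calcium_foci,
                 compass_diameter_mm = compass_diameter_mm,
                 compass_intensity = compass_intensity,
                 anti_alias = isTRUE(anti_alias),
                 seed = as.integer(seed)),
            class = "render_spec")
}

#' Render a contour as a synthetic calibrated CT slice
#'
#' Pixels whose centers fall inside the contour get the lumen intensity,
#' all others the tissue intensity; calcium foci overwrite the intersection
#' of their disk with the lumen; an optional compass ring of known physical
#' diameter is drawn centered in the image; Gaussian noise is added last and
#' the result is rounded and truncated to the 16-bit range.
#'
#' @param contour a [contour_polyline()] in mm, image coordinate frame.
#' @param spec a [render_spec()].
#' @param plane,phase,subject_id metadata stored on the image.
#' @return A [calibrated_image()].
#' @export
render_ct_slice <- function(contour, spec = render_spec(), plane = "annulus",
                            phase = "diastole", subject_id = NA_character_) {
  stopifnot(inherits(contour, "contour_polyline"),
            inherits(spec, "render_spec"))
  nr <- spec$image_size_px[1]
  nc <- spec$image_size_px[2]
  mmpp <- spec$mm_per_pixel
  xp <- contour$x / mmpp
  yp <- contour$y / mmpp
  if (min(xp) < 0 || min(yp) < 0 || max(xp) > nc - 1 || max(yp) > nr - 1) {
    abort_afd("contour exceeds image bounds at this scale", "invalid_parameter")
  }
  if (spec$anti_alias) {
    # partial-volume model: pixel intensity mixes lumen and tissue by the
    # area fraction the lumen occupies in the pixel (4x4 subsampling)
    S <- 4L
    fine <- cpp_fill_polygon(xp * S + (S - 1) / 2, yp * S + (S - 1) / 2,
                             nr * S, nc * S)
    rsum <- rowsum(fine + 0, rep(seq_len(nr), each = S))
    csum <- t(rowsum(t(rsum), rep(seq_len(nc), each = S)))
    coverage <- csum / S^2
    inside <- coverage >= 0.5
    img <- spec$tissue_intensity +
      coverage * (spec$lumen_intensity - spec$tissue_intensity)
  } else {
    inside <- cpp_fill_polygon(xp, yp, nr, nc)
    img <- matrix(spec$tissue_intensity, nr, nc)
    img[inside] <- spec$lumen_intensity
  }
  if (length(spec$calcium_foci)) {
    colx <- matrix((seq_len(nc) - 1) * mmpp, nr, nc, byrow = TRUE)
    rowy <- matrix((seq_len(nr) - 1) * mmpp, nr, nc)
    for (focus in spec$calcium_foci) {
      d2 <- (colx - focus$center[1])^2 + (rowy - focus$center[2])^2
      hit <- d2 <= focus$radius_mm^2 & inside   # clip against the lumen
      img[hit] <- focus$intensity
    }
  }
  if (!is.null(spec$compass_diameter_mm)) {
    r_px <- spec$compass_diameter_mm / 2 / mmpp
    ctr <- c((nc - 1) / 2, (nr - 1) / 2)
    dc <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE) - ctr[1]
    dr <- matrix(seq_len(nr) - 1, nr, nc) - ctr[2]
    ring <- abs(sqrt(dc^2 + dr^2) - r_px) <= 0.5
    img[ring] <- spec$compass_intensity
  }
  if (spec$noise_sd > 0) {
    img <- img + withr::with_seed(spec$seed,
                                  stats::rnorm(nr * nc, 0, spec$noise_sd))
  }
  img <- matrix(pmin(pmax(round(img), 0), 65535), nr, nc)
  calibrated_image(img, mmpp, plane = plane, phase = phase,
                   subject_id = subject_id)
}
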