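#' Euclidean measures of a closed contour
#'
#' The conventional morphometry the fractal dimension is compared against:
#' shoelace area, vertex-chain perimeter, maximal Feret diameter (largest
#' vertex-pair distance), minimal Feret width (smallest width over
#' rotating-calipers directions on the convex hull), and eccentricity
#' `100 * (d_max - d_min) / d_max`. Feret-type diameters are a package
#' definition: they are rotation-invariant and deterministic, but whether
#' clinical workstations use Feret or centroid-ray diameters is not
#' documented.
#'
#' @param contour a simple closed [contour_polyline()].
#' @return An object of class `geometry_measures`: `area_mm2`,
#'   `perimeter_mm`, `d_min_mm`, `d_max_mm`, `eccentricity_pct`.
#' @export
contour_measures <- function(contour) {
  stopifnot(inherits(contour, "contour_polyline"))
  if (!contour_is_simple(contour)) {
    abort_afd("contour is self-intersecting", "invalid_contour")
  }
  x <- contour$x
  y <- contour$y
  n <- length(x)
  nx <- c(2:n, 1)
  area <- abs(sum(x * y[nx] - x[nx] * y)) / 2
  perimeter <- sum(sqrt((x[nx] - x)^2 + (y[nx] - y)^2))
  hull <- grDevices::chull(x, y)
  hx <- x[hull]
  hy <- y[hull]
  h <- length(hull)
  d_max <- sqrt(max(outer(hx, hx, "-")^2 + outer(hy, hy, "-")^2))
  # rotating calipers: min over hull edges of the max point distance to the
  # edge's supporting line
  hnx <- c(2:h, 1)
  ex <- hx[hnx] - hx
  ey <- hy[hnx] - hy
  elen <- sqrt(ex^2 + ey^2)
  ok <- elen > 0
  widths <- vapply(which(ok), function(i) {
    max(abs((x - hx[i]) * ey[i] - (y - hy[i]) * ex[i])) / elen[i]
  }, numeric(1))
  d_min <- min(widths)
  ecc <- 100 * (d_max - d_min) / d_max
  structure(list(area_mm2 = area, perimeter_mm = perimeter,
                 d_min_mm = d_min, d_max_mm = d_max,
                 eccentricity_pct = ecc),
            class = "geometry_measures")
}

#' @export
print.geometry_measures <- function(x, ...) {
  cat(sprintf(
    "<geometry_measures> area %.2f mm², perimeter %.2f mm, d %.2f–%.2f mm, ecc %.1f%%\n",
    x$area_mm2, x$perimeter_mm, x$d_min_mm, x$d_max_mm, x$eccentricity_pct))
  invisible(x)
}

#' LVOT non-tubularity
#'
#' Taper measure of the prosthesis landing zone:
#' `(annulus area - LVOT area) / annulus area`. Negative values (an LVOT
#' larger than the annulus, i.e. flaring) are passed through unclamped.
#'
#' @param annulus_area_mm2 annular cross-sectional area, positive.
#' @param lvot_area_mm2 LVOT cross-sectional area, non-negative.
#' @return Dimensionless ratio.
#' @export
non_tubularity <- function(annulus_area_mm2, lvot_area_mm2) {
  if (!is.numeric(annulus_area_mm2) || annulus_area_mm2 <= 0) {
    abort_afd("annulus area must be positive", "invalid_parameter")
  }
  if (!is.numeric(lvot_area_mm2) || lvot_area_mm2 < 0) {
    abort_afd("LVOT area must be non-negative", "invalid_parameter")
  }
  (annulus_area_mm2 - lvot_area_mm2) / annulus_area_mm2
}
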