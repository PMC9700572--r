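#' Closed planar contour in millimetres
#'
#' A `contour_polyline` is an ordered, closed sequence of 2D vertices in mm.
#' The closing edge from the last vertex back to the first is implicit: the
#' vertex list must not repeat the first vertex at the end.
#'
#' @param x,y numeric vertex coordinates in mm, equal length, at least 3.
#' @param validate check finiteness and vertex count.
#' @return An object of class `contour_polyline` with fields `x` and `y`.
#' @export
contour_polyline <- function(x, y, validate = TRUE) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (validate) {
    if (length(x) != length(y)) {
      abort_afd("x and y must have equal length", "invalid_contour")
    }
    if (length(x) >= 2 && x[1] == x[length(x)] && y[1] == y[length(y)]) {
      x <- x[-length(x)]
      y <- y[-length(y)]
    }
    if (length(x) < 3) {
      abort_afd("a contour needs at least 3 vertices", "invalid_contour")
    }
    if (any(!is.finite(x)) || any(!is.finite(y))) {
      abort_afd("contour vertices must be finite", "invalid_contour")
    }
  }
  structure(list(x = x, y = y), class = "contour_polyline")
}

#' @export
print.contour_polyline <- function(x, ...) {
  cat(sprintf(
    "<contour_polyline> %d vertices, bbox [%.2f, %.2f] x [%.2f, %.2f] mm\n",
    length(x$x), min(x$x), max(x$x), min(x$y), max(x$y)
  ))
  invisible(x)
}

#' @export
as.data.frame.contour_polyline <- function(x, ...) {
  data.frame(x_mm = x$x, y_mm = x$y)
}

#' Test a closed contour for self-intersection
#'
#' Pairwise segment sweep over all non-adjacent edge pairs, including the
#' implicit closing edge. Touching counts as intersecting.
#'
#' @param contour a [contour_polyline()].
#' @return `TRUE` if the contour is simple (no self-intersection).
#' @export
contour_is_simple <- function(contour) {
  stopifnot(inherits(contour, "contour_polyline"))
  !cpp_self_intersects(contour$x, contour$y)
}

#' Translate a contour
#' @param contour a [contour_polyline()].
#' @param dx,dy translation in mm.
#' @export
translate_contour <- function(contour, dx, dy) {
  contour_polyline(contour$x + dx, contour$y + dy, validate = FALSE)
}

#' Regular-polygon approximation of a circle
#'
#' The smooth-curve limit used as a fractal-dimension oracle: a rectifiable
#' smooth closed curve has box-counting dimension 1.
#'
#' @param radius_mm circle radius in mm, positive.
#' @param n_vertices number of vertices, at least 16.
#' @param center circle center `c(x, y)` in mm.
#' @return A [contour_polyline()] whose vertices lie on the circle.
#' @export
generate_circle_contour <- function(radius_mm, n_vertices = 360,
                                    center = c(0, 0)) {
  if (!is.numeric(radius_mm) || length(radius_mm) != 1 || radius_mm <= 0) {
    abort_afd("radius_mm must be a positive number", "invalid_parameter")
  }
  if (n_vertices < 16) {
    abort_afd("n_vertices must be >= 16", "invalid_parameter")
  }
  theta <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  contour_polyline(center[1] + radius_mm * cos(theta),
                   center[2] + radius_mm * sin(theta))
}

#' Koch snowflake boundary
#'
#' Exact-fractal oracle: the similarity dimension of the Koch curve is
#' ln(4)/ln(3) = 1.26186. Level `k` has `3 * 4^k` segments; the smallest
#' segment is `side_mm / 3^k`, which bounds the scaling regime from below.
#'
#' @param level recursion depth, 0 to 7 (vertex count grows as 4^level).
#' @param side_mm side length of the level-0 triangle in mm.
#' @param center snowflake center `c(x, y)` in mm.
#' @return A [contour_polyline()] traversed counterclockwise.
#' @export
generate_koch_contour <- function(level, side_mm = 54, center = c(0, 0)) {
  if (!is.numeric(level) || length(level) != 1 || level != round(level) ||
      level < 0) {
    abort_afd("level must be a non-negative integer", "invalid_parameter")
  }
  if (level > 7) {
    abort_afd("level > 7 refused: vertex count would explode",
              "invalid_parameter")
  }
  if (side_mm <= 0) abort_afd("side_mm must be positive", "invalid_parameter")
  # counterclockwise equilateral triangle, centroid at origin
  r <- side_mm / sqrt(3)
  ang <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
  x <- r * cos(ang)
  y <- r * sin(ang)
  for (i in seq_len(level)) {
    n <- length(x)
    jn <- c(seq_len(n)[-1], 1L)
    ax <- x; ay <- y
    bx <- x[jn]; by <- y[jn]
    ux <- (bx - ax) / 3; uy <- (by - ay) / 3
    p1x <- ax + ux;      p1y <- ay + uy
    p3x <- ax + 2 * ux;  p3y <- ay + 2 * uy
    # outward bump: rotate the middle third by -60 deg (right of travel for CCW)
    c60 <- cos(-pi / 3); s60 <- sin(-pi / 3)
    p2x <- p1x + ux * c60 - uy * s60
    p2y <- p1y + ux * s60 + uy * c60
    x <- as.vector(rbind(ax, p1x, p2x, p3x))
    y <- as.vector(rbind(ay, p1y, p2y, p3y))
  }
  contour_polyline(center[1] + x, center[2] + y)
}

#' Specification of a synthetic fractal annulus contour
#'
#' The contour is a radial perturbation of a circle,
#' `r(theta) = R * (1 + a * f_H(theta))`, where `f_H` is a zero-mean periodic
#' profile built by Fourier synthesis with power-law amplitude spectrum
#' `|c_k| ~ k^(-H - 1/2)` and uniform random phases, normalised to unit RMS.
#' Lower Hurst exponent `H` or larger amplitude `a` gives a rougher border and
#' a higher box-counting dimension.
#'
#' @param base_radius_mm mean radius `R` in mm, positive.
#' @param roughness_amplitude `a`, RMS radial perturbation as a fraction of
#'   `R`; 0 gives an exact circle polygon.
#' @param hurst_exponent `H` in (0, 1].
#' @param n_vertices number of vertices, at least 16.
#' @param seed integer seed; identical spec gives bit-identical contours.
#' @param center contour center `c(x, y)` in mm.
#' @return An object of class `contour_spec`.
#' @export
contour_spec <- function(base_radius_mm = 12, roughness_amplitude = 0.05,
                         hurst_exponent = 0.5, n_vertices = 256, seed = 1,
                         center = c(0, 0)) {
  if (base_radius_mm <= 0) {
    abort_afd("base_radius_mm must be positive", "invalid_parameter")
  }
  if (roughness_amplitude < 0) {
    abort_afd("roughness_amplitude must be non-negative", "invalid_parameter")
  }
  if (hurst_exponent <= 0 || hurst_exponent > 1) {
    abort_afd("hurst_exponent must be in (0, 1]", "invalid_parameter")
  }
  if (n_vertices < 16) abort_afd("n_vertices must be >= 16", "invalid_parameter")
  structure(list(base_radius_mm = base_radius_mm,
                 roughness_amplitude = roughness_amplitude,
                 hurst_exponent = hurst_exponent,
                 n_vertices = as.integer(n_vertices),
                 seed = as.integer(seed),
                 center = center),
            class = "contour_spec")
}

# zero-mean, unit-RMS periodic fractional-noise profile at n sample angles
fractional_profile <- function(n, hurst, seed) {
  kmax <- max(3L, n %/% 4L)      # >= 4 samples per wavelength
  k <- 2:kmax                    # k = 1 is mostly a translation; excluded
  amp <- k^(-hurst - 0.5)
  phases <- withr::with_seed(seed, stats::runif(length(k), 0, 2 * pi))
  theta <- 2 * pi * (seq_len(n) - 1) / n
  f <- as.vector(cos(outer(theta, k) + rep(phases, each = n)) %*% amp)
  f <- f - mean(f)
  f / sqrt(mean(f^2))
}

#' Generate a synthetic fractal annulus contour
#'
#' Draws the radial profile described in [contour_spec()], rejects
#' self-intersecting or non-positive-radius realisations, and resamples with
#' a perturbed seed up to 10 times before failing.
#'
#' @param spec a [contour_spec()].
#' @return A simple closed [contour_polyline()].
#' @export
generate_fractal_contour <- function(spec) {
  stopifnot(inherits(spec, "contour_spec"))
  if (spec$roughness_amplitude == 0) {
    return(generate_circle_contour(spec$base_radius_mm, spec$n_vertices,
                                   spec$center))
  }
  theta <- 2 * pi * (seq_len(spec$n_vertices) - 1) / spec$n_vertices
  for (attempt in 0:9) {
    sub_seed <- (spec$seed + 7919L * attempt) %% .Machine$integer.max
    f <- fractional_profile(spec$n_vertices, spec$hurst_exponent, sub_seed)
    r <- spec$base_radius_mm * (1 + spec$roughness_amplitude * f)
    if (any(r <= 0)) next
    x <- spec$center[1] + r * cos(theta)
    y <- spec$center[2] + r * sin(theta)
    if (!cpp_self_intersects(x, y)) {
      return(contour_polyline(x, y, validate = FALSE))
    }
  }
  abort_afd("could not draw a simple contour in 10 attempts; lower roughness_amplitude",
            "generation_failure")
}

#' Write / read a contour as a two-column CSV of mm coordinates
#'
#' One contour per file, columns `x_mm` and `y_mm`, so manually corrected
#' borders can be round-tripped through external tools.
#'
#' @param contour a [contour_polyline()].
#' @param path file path.
#' @export
write_contour_csv <- function(contour, path) {
  utils::write.csv(as.data.frame(contour), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_csv <- function(path) {
  df <- utils::read.csv(path)
  contour_polyline(df$x_mm, df$y_mm)
}
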