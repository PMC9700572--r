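# Independent oracles used to cross-check the package's primitives.

# Exhaustive box-count oracle: tests EVERY grid box in the bounding region
# against EVERY segment of the closed polyline. Occupancy rule mirrors the
# package contract: a box counts when the intersection with the polyline has
# positive length (closed boxes, shared-edge segments count for both sides,
# bare point touches do not). The per-pair predicate clips the segment
# parameter interval axis by axis with explicit case analysis.
brute_force_box_count <- function(contour, caliber, origin = c(0, 0)) {
  x <- contour$x
  y <- contour$y
  n <- length(x)
  nx <- c(2:n, 1)
  i_lo <- floor((min(x) - origin[1]) / caliber) - 1
  i_hi <- floor((max(x) - origin[1]) / caliber) + 1
  j_lo <- floor((min(y) - origin[2]) / caliber) - 1
  j_hi <- floor((max(y) - origin[2]) / caliber) + 1
  axis_interval <- function(p, d, lo, hi) {
    if (d == 0) {
      if (p < lo || p > hi) c(1, 0) else c(0, 1)
    } else if (d > 0) {
      c((lo - p) / d, (hi - p) / d)
    } else {
      c((hi - p) / d, (lo - p) / d)
    }
  }
  occupied <- 0L
  for (bi in i_lo:i_hi) {
    for (bj in j_lo:j_hi) {
      bx <- origin[1] + bi * caliber
      by <- origin[2] + bj * caliber
      hit <- FALSE
      for (s in seq_len(n)) {
        tx <- axis_interval(x[s], x[nx[s]] - x[s], bx, bx + caliber)
        ty <- axis_interval(y[s], y[nx[s]] - y[s], by, by + caliber)
        t0 <- max(0, tx[1], ty[1])
        t1 <- min(1, tx[2], ty[2])
        if (t1 - t0 > 1e-12) {
          hit <- TRUE
          break
        }
      }
      if (hit) occupied <- occupied + 1L
    }
  }
  occupied
}

# Monte-Carlo area oracle: fraction of uniform points inside the polygon
# (even-odd ray crossing), scaled by the bounding-box area.
mc_polygon_area <- function(contour, n_points = 2e5, seed = 42) {
  bx <- range(contour$x)
  by <- range(contour$y)
  pts <- withr::with_seed(seed, cbind(stats::runif(n_points, bx[1], bx[2]),
                                      stats::runif(n_points, by[1], by[2])))
  x <- contour$x
  y <- contour$y
  n <- length(x)
  nx <- c(2:n, 1)
  inside <- vapply(seq_len(n_points), function(i) {
    px <- pts[i, 1]
    py <- pts[i, 2]
    crossings <- sum((y <= py & y[nx] > py | y[nx] <= py & y > py) &
                       (x + (py - y) / (y[nx] - y) * (x[nx] - x) > px))
    crossings %% 2 == 1
  }, logical(1))
  mean(inside) * diff(bx) * diff(by)
}

# standard two-group parameter sets for cohort simulations
null_params <- function(a = 0.03) {
  list(g0 = list(base_radius_mm = 12, roughness_amplitude = a,
                 hurst_exponent = 0.4),
       g1 = list(base_radius_mm = 12, roughness_amplitude = a,
                 hurst_exponent = 0.4))
}

planted_params <- function(a_neg = 0.01, a_pos = 0.03) {
  list(g0 = list(base_radius_mm = 12, roughness_amplitude = a_neg,
                 hurst_exponent = 0.4),
       g1 = list(base_radius_mm = 12, roughness_amplitude = a_pos,
                 hurst_exponent = 0.4))
}

outcome_labels <- function() {
  list(g0 = list(pvr_grade = "none", composite_endpoint = FALSE),
       g1 = list(pvr_grade = "mild", composite_endpoint = TRUE))
}
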