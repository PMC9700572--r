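# shared fixture: a circle rendered at high resolution with a compass ring
seg_fixture <- local({
  ct <- generate_circle_contour(12, 720, center = c(25.55, 25.55))
  sp <- render_spec(mm_per_pixel = 0.1, image_size_px = c(512, 512),
                    compass_diameter_mm = 50)
  list(contour = ct, image = render_ct_slice(ct, sp))
})

test_that("luminal attenuation gate reports the probe median and verdict", {
  img <- seg_fixture$image
  g <- check_luminal_attenuation(img)
  expect_equal(g$value, 400)
  expect_true(g$suitable)
  dim_ct <- render_ct_slice(seg_fixture$contour,
                            render_spec(mm_per_pixel = 0.1,
                                        image_size_px = c(512, 512),
                                        lumen_intensity = 250))
  g2 <- check_luminal_attenuation(dim_ct)
  expect_equal(g2$value, 250)
  expect_false(g2$suitable)
  # exactly at the gate is not above it
  at_gate <- check_luminal_attenuation(img, gate = 400)
  expect_false(at_gate$suitable)
  expect_error(check_luminal_attenuation(img, probe = c(-5, 10)),
               class = "annulusFD_invalid_parameter")
})

test_that("compass calibration recovers the scale within 1%", {
  expect_equal(calibrate_from_compass(seg_fixture$image, 50), 0.1,
               tolerance = 0.01)
  # 200 px ring with known 10 mm -> 0.05 mm/px
  ct <- generate_circle_contour(3, 90, center = c(7.975, 7.975))
  img2 <- render_ct_slice(ct, render_spec(mm_per_pixel = 0.05,
                                          image_size_px = c(320, 320),
                                          compass_diameter_mm = 10))
  expect_equal(calibrate_from_compass(img2, 10), 0.05, tolerance = 0.01)
  no_ring <- render_ct_slice(ct, render_spec(mm_per_pixel = 0.05,
                                             image_size_px = c(320, 320)))
  expect_error(calibrate_from_compass(no_ring, 10),
               class = "annulusFD_calibration_failure")
})

test_that("border detection round-trips area within 2% and perimeter within 4%", {
  specs <- list(contour_spec(12, 0.03, 0.4, 128, seed = 11),
                contour_spec(10, 0.06, 0.6, 128, seed = 12),
                contour_spec(14, 0.04, 0.3, 96, seed = 13))
  for (mp in c(0.1, 0.2)) {
    for (cs in specs) {
      n <- round(51.2 / mp)
      cs$center <- c((n - 1) / 2, (n - 1) / 2) * mp
      truth <- generate_fractal_contour(cs)
      img <- render_ct_slice(truth, render_spec(mm_per_pixel = mp,
                                                image_size_px = c(n, n)))
      got <- contour_measures(detect_border(img))
      want <- contour_measures(truth)
      expect_lt(abs(got$area_mm2 / want$area_mm2 - 1), 0.02)
      expect_lt(abs(got$perimeter_mm / want$perimeter_mm - 1), 0.04)
    }
  }
})

test_that("calcium indentation strictly reduces the segmented area", {
  ct <- seg_fixture$contour
  sp <- render_spec(mm_per_pixel = 0.1, image_size_px = c(512, 512),
                    calcium_foci = list(list(center = c(37.55, 25.55),
                                             radius_mm = 3, intensity = 1200)))
  a_plain <- contour_measures(detect_border(seg_fixture$image))$area_mm2
  a_calc <- contour_measures(detect_border(render_ct_slice(ct, sp)))$area_mm2
  expect_lt(a_calc, a_plain)
})

test_that("seed, open-boundary and fragmentation failures are classed", {
  img <- seg_fixture$image
  expect_error(detect_border(img, lumen_seed = c(2, 2)),
               class = "annulusFD_seed_error")
  expect_error(detect_border(img, lumen_seed = c(-1, 2)),
               class = "annulusFD_invalid_parameter")
  # lumen clipped by the frame -> open boundary
  open_px <- matrix(50, 100, 100)
  open_px[1:60, 30:70] <- 400
  img_open <- calibrated_image(open_px, 0.1)
  expect_error(detect_border(img_open), class = "annulusFD_open_boundary")
  # two comparably sized disconnected bright regions -> fragmentation
  frag_px <- matrix(50, 100, 100)
  frag_px[30:70, 10:45] <- 400
  frag_px[30:70, 55:90] <- 400
  frag_img <- calibrated_image(frag_px, 0.1)
  expect_error(detect_border(frag_img, lumen_seed = c(2.5, 5.0)),
               class = "annulusFD_fragmentation")
})

test_that("raising the threshold never grows the segmented area", {
  ct <- generate_fractal_contour(contour_spec(11, 0.05, 0.5, 128, seed = 4,
                                              center = c(25.55, 25.55)))
  img <- render_ct_slice(ct, render_spec(mm_per_pixel = 0.1,
                                         image_size_px = c(512, 512)))
  areas <- vapply(c(150, 250, 350, 395), function(th) {
    contour_measures(detect_border(img, threshold = th,
                                   trace_level = "threshold"))$area_mm2
  }, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("pixel-chain mode traces a coarser but consistent boundary", {
  sub <- detect_border(seg_fixture$image)
  chain <- detect_border(seg_fixture$image, subpixel = FALSE)
  expect_equal(attr(chain, "method"), "pixel_chain")
  a1 <- contour_measures(sub)$area_mm2
  a2 <- contour_measures(chain)$area_mm2
  expect_lt(abs(a2 / a1 - 1), 0.02)
})

test_that("manual override validates closure and simplicity", {
  img <- seg_fixture$image
  tri <- data.frame(x_mm = c(10, 30, 20), y_mm = c(10, 10, 30))
  got <- override_contour(img, tri)
  expect_equal(attr(got, "method"), "manual")
  expect_length(got$x, 3)
  expect_error(override_contour(img, tri[1:2, ]),
               class = "annulusFD_invalid_parameter")
  eight <- data.frame(x_mm = c(0, 10, 10, 0), y_mm = c(0, 10, 0, 10))
  expect_error(override_contour(img, eight),
               class = "annulusFD_invalid_contour")
})

test_that("FD is calibration-independent across rendering scales", {
  cs <- contour_spec(12, 0.05, 0.5, 128, seed = 31)
  fds <- vapply(c(0.1, 0.2), function(mp) {
    n <- round(51.2 / mp)
    cs$center <- c((n - 1) / 2, (n - 1) / 2) * mp
    truth <- generate_fractal_contour(cs)
    img <- render_ct_slice(truth, render_spec(mm_per_pixel = mp,
                                              image_size_px = c(n, n)))
    compute_fd(detect_border(img))$fd
  }, numeric(1))
  expect_lt(abs(fds[1] - fds[2]), 0.01)
})
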