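test_that("cohort generation is seeded, labeled, and validates sizes", {
  c1 <- generate_cohort(3, planted_params(), outcome_labels(), seed = 5)
  c2 <- generate_cohort(3, planted_params(), outcome_labels(), seed = 5)
  expect_identical(c1, c2)
  c3 <- generate_cohort(3, planted_params(), outcome_labels(), seed = 6)
  expect_false(identical(c1, c3))
  expect_length(c1, 6)
  expect_setequal(unique(vapply(c1, `[[`, "", "group")), c("g0", "g1"))
  expect_named(c1[[1]]$cells,
               c("annulus.systole", "lvot.systole", "annulus.diastole",
                 "lvot.diastole"))
  expect_equal(c1[[4]]$pvr_grade, "mild")
  expect_error(generate_cohort(0, planted_params(), outcome_labels()),
               class = "annulusFD_invalid_parameter")
  expect_error(generate_cohort(3, planted_params()["g0"], outcome_labels()),
               class = "annulusFD_invalid_parameter")
})

test_that("missing-phase pattern drops cells but keeps subjects", {
  co <- generate_cohort(10, planted_params(), outcome_labels(), seed = 9,
                        missing_rate = 0.4)
  n_cells <- vapply(co, function(s) length(s$cells), integer(1))
  expect_lt(sum(n_cells), 10 * 2 * 4)
  expect_length(co, 20)
})

test_that("demo pipeline runs end to end and reproduces byte-identically", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  b1 <- make_demo(file.path(dir1, "demo"), seed = 4, n_per_group = 4)
  b2 <- make_demo(file.path(dir2, "demo"), seed = 4, n_per_group = 4)
  for (f in c("analysis/results.csv", "analysis/curves.csv",
              "analysis/stats.json")) {
    expect_identical(readLines(file.path(dir1, "demo", f)),
                     readLines(file.path(dir2, "demo", f)),
                     label = f)
  }
  expect_equal(unname(b1$counts["input"]),
               unname(b1$counts["analyzed"] + b1$counts["excluded"]))
  expect_identical(unname(b1$counts["excluded"]), 0L)
  # expected-signature sidecar is present and machine readable
  exp <- jsonlite::read_json(b1$expected)
  expect_equal(exp$planted_contrast, "annulus.diastole")
  # all four plane x phase cells were measured and the report exists
  expect_identical(nrow(b1$report$table), 4L)
  expect_true(all(b1$results$r_squared > 0.9))
})

test_that("corrupt and unsuitable images are excluded with reconciled counts", {
  root <- withr::local_tempdir()
  cohort <- generate_cohort(2, planted_params(), outcome_labels(), seed = 13,
                            planes = "annulus", phases = "diastole",
                            render = TRUE)
  manifest_path <- write_cohort(cohort, root)
  manifest <- utils::read.csv(manifest_path)
  # corrupt one image on disk
  writeLines("garbage", file.path(root, manifest$image_path[1]))
  config <- pipeline_config(compass_diameter_mm = 30,
                            out_dir = file.path(root, "analysis"))
  bundle <- run_pipeline(manifest_path, config)
  expect_equal(unname(bundle$counts["input"]), 4)
  expect_equal(unname(bundle$counts["excluded"]), 1)
  expect_equal(unname(bundle$counts["analyzed"]), 3)
  res <- bundle$results
  expect_identical(res$status[1], "excluded")
  expect_identical(res$reason[1], "io_error")
  log <- readLines(file.path(root, "analysis", "run.log"))
  expect_true(any(grepl("EXCLUDE", log)))
  expect_true(any(grepl("input=4 analyzed=3 excluded=1", log)))
})

test_that("gate failures are excluded with a machine-readable reason", {
  root <- withr::local_tempdir()
  ct <- generate_circle_contour(10, 180, center = c(21.9, 21.9))
  dim_img <- render_ct_slice(ct, render_spec(mm_per_pixel = 0.2,
                                             image_size_px = c(220, 220),
                                             lumen_intensity = 250,
                                             compass_diameter_mm = 30))
  write_calibrated_image(dim_img, file.path(root, "dim.tif"))
  bright <- render_ct_slice(ct, render_spec(mm_per_pixel = 0.2,
                                            image_size_px = c(220, 220),
                                            compass_diameter_mm = 30))
  write_calibrated_image(bright, file.path(root, "ok.tif"))
  manifest <- data.frame(subject_id = c("S1", "S2"),
                         plane = "annulus", phase = "diastole",
                         image_path = file.path(root, c("dim.tif", "ok.tif")))
  config <- pipeline_config(compass_diameter_mm = 30,
                            out_dir = file.path(root, "out"))
  bundle <- run_pipeline(manifest, config)
  expect_identical(bundle$results$reason, c("gate_failure", ""))
  # a manifest where every image fails the gate is a hard error
  config2 <- pipeline_config(compass_diameter_mm = 30,
                             out_dir = file.path(root, "out2"))
  expect_error(run_pipeline(manifest[1, , drop = FALSE], config2),
               class = "annulusFD_all_unsuitable")
})

test_that("config echo round-trips through JSON", {
  root <- withr::local_tempdir()
  cohort <- generate_cohort(2, planted_params(), outcome_labels(), seed = 3,
                            planes = "annulus", phases = "diastole",
                            render = TRUE)
  manifest <- write_cohort(cohort, root)
  config <- pipeline_config(compass_diameter_mm = 30, n_calibers = 8,
                            out_dir = file.path(root, "a1"))
  run_pipeline(manifest, config)
  cfg2 <- read_pipeline_config(file.path(root, "a1", "config.json"))
  cfg2$out_dir <- file.path(root, "a2")
  run_pipeline(manifest, cfg2)
  expect_identical(readLines(file.path(root, "a1", "results.csv")),
                   readLines(file.path(root, "a2", "results.csv")))
})

test_that("the CLI surfaces the demo and run subcommands", {
  root <- withr::local_tempdir()
  out <- file.path(root, "demo")
  expect_output(annulusfd_cli(c("demo", "--out", out, "--seed", "2",
                                "--n", "3")), "demo written")
  expect_true(file.exists(file.path(out, "analysis", "results.csv")))
  out2 <- file.path(root, "rerun")
  expect_output(annulusfd_cli(c("run", "--manifest",
                                file.path(out, "manifest.csv"),
                                "--compass", "30", "--out", out2)),
                "analyzed=")
  expect_true(file.exists(file.path(out2, "stats.json")))
  expect_output(res <- annulusfd_cli(character(0)), "usage")
  expect_identical(res, 1L)
})

test_that("simulated FD cohorts feed compare_cohort deterministically", {
  recs <- simulate_fd_cohort(5, planted_params(), outcome_labels(), seed = 8)
  recs2 <- simulate_fd_cohort(5, planted_params(), outcome_labels(), seed = 8)
  expect_identical(recs, recs2)
  rep <- compare_cohort(recs)
  expect_identical(rep$target, "annulus.diastole")
  expect_true(is.finite(rep$roc$auc))
})
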