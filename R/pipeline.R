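#' Pipeline configuration
#'
#' Serializable bundle of every tunable the pipeline uses; a run echoes its
#' config as JSON into the output directory so results are reproducible from
#' the artifact alone.
#'
#' @param caliber_range,n_calibers,grid_origin see [fd_config()].
#' @param threshold,calcium_ceiling see [detect_border()].
#' @param gate suitability gate, see [check_luminal_attenuation()].
#' @param compass_diameter_mm known compass-ring diameter for calibration,
#'   or `NULL` to rely on per-image `mm_per_pixel`.
#' @param mm_per_pixel fallback scale when no compass ring is available.
#' @param grouping,target see [compare_cohort()].
#' @param seed master seed for anything stochastic.
#' @param out_dir output directory.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(caliber_range = c(0.8, 6.75), n_calibers = 10,
                            grid_origin = c(0, 0), threshold = 300,
                            calcium_ceiling = 800, gate = 300,
                            compass_diameter_mm = NULL, mm_per_pixel = NULL,
                            grouping = "pvr",
                            target = c("annulus", "diastole"), seed = 1,
                            out_dir = "annulusFD_out") {
  structure(list(caliber_range = caliber_range,
                 n_calibers = as.integer(n_calibers),
                 grid_origin = grid_origin, threshold = threshold,
                 calcium_ceiling = calcium_ceiling, gate = gate,
                 compass_diameter_mm = compass_diameter_mm,
                 mm_per_pixel = mm_per_pixel, grouping = grouping,
                 target = target, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline config back from its JSON echo
#' @param path path to a `config.json` written by [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  lst$compass_diameter_mm <- if (is.null(lst$compass_diameter_mm) ||
                                 !length(lst$compass_diameter_mm)) NULL
                             else lst$compass_diameter_mm
  lst$mm_per_pixel <- if (is.null(lst$mm_per_pixel) ||
                          !length(lst$mm_per_pixel)) NULL
                      else lst$mm_per_pixel
  do.call(pipeline_config, lst)
}

#' Write a rendered cohort to disk as TIFFs plus a manifest CSV
#'
#' @param cohort output of [generate_cohort()] with `render = TRUE`.
#' @param out_dir directory to create.
#' @return Path to the manifest CSV (columns `subject_id`, `plane`, `phase`,
#'   `image_path`, `group`, `pvr_grade`, `composite_endpoint`).
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  rows <- list()
  for (su in cohort) {
    for (cell in names(su$cells)) {
      img <- su$cells[[cell]]
      if (!inherits(img, "calibrated_image")) {
        abort_afd("write_cohort needs a rendered cohort (render = TRUE)",
                  "invalid_parameter")
      }
      rel <- file.path("images", sprintf("%s_%s.tif", su$subject_id, cell))
      write_calibrated_image(img, file.path(out_dir, rel))
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = su$subject_id, plane = img$plane, phase = img$phase,
        image_path = rel, group = su$group, pvr_grade = su$pvr_grade,
        composite_endpoint = su$composite_endpoint)
    }
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  path
}

# deterministic CSV writer (fixed significant digits, no row names)
write_csv_out <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) {
    ifelse(is.na(v), NA_character_, formatC(v, digits = 12, format = "g"))
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Run the full measurement pipeline over a manifest
#'
#' For each manifest row: read the TIFF, establish the mm-per-pixel scale
#' (manifest column, then compass ring, then config fallback), apply the
#' luminal-attenuation gate, detect the border, and compute fractal
#' dimension and Euclidean geometry. Failures are logged and the image
#' excluded with a machine-readable reason; the run maintains the accounting
#' identity `n_input = n_analyzed + n_excluded`. When group labels are
#' present the cohort statistics layer is run on the per-subject FD values.
#'
#' @param manifest path to a manifest CSV (columns `subject_id`, `plane`,
#'   `phase`, `image_path`, optional `group`, `pvr_grade`,
#'   `composite_endpoint`, `mm_per_pixel`, `seed_x`, `seed_y`) or an
#'   equivalent data frame (then image paths must be absolute or relative to
#'   the working directory).
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `results` (per-image data frame), `curves`
#'   (box-count long table), `report` (a [compare_cohort()] result or
#'   `NULL`), `counts` (input/analyzed/excluded), and `out_dir`. Artifacts
#'   written: `results.csv`, `curves.csv`, `stats.json`, `config.json`,
#'   `run.log`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config()) {
  base_dir <- "."
  if (is.character(manifest)) {
    base_dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_msg <- function(...) {
    log_lines[[length(log_lines) + 1]] <<- sprintf(...)
  }
  fdc <- fd_config(caliber_range = config$caliber_range,
                   n_calibers = config$n_calibers,
                   grid_origin = config$grid_origin)
  res_rows <- list()
  curve_rows <- list()
  records <- list()
  n_excluded <- 0L
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    cell <- paste(row$plane, row$phase, sep = ".")
    tag <- sprintf("%s/%s", row$subject_id, cell)
    status <- "analyzed"
    reason <- ""
    fd_fit <- NULL
    geom <- NULL
    gate_value <- NA_real_
    tryCatch({
      img_path <- if (grepl("^(/|[A-Za-z]:)", row$image_path)) row$image_path
                  else file.path(base_dir, row$image_path)
      img <- read_calibrated_image(img_path,
                                   plane = row$plane, phase = row$phase,
                                   subject_id = row$subject_id)
      img$mm_per_pixel <-
        if (!is.null(row$mm_per_pixel) && length(row$mm_per_pixel) &&
            is.finite(row$mm_per_pixel)) {
          as.numeric(row$mm_per_pixel)
        } else if (!is.null(config$compass_diameter_mm)) {
          calibrate_from_compass(img, config$compass_diameter_mm)
        } else if (!is.null(config$mm_per_pixel)) {
          config$mm_per_pixel
        } else {
          abort_afd("no mm_per_pixel source (manifest, compass, or config)",
                    "calibration_failure")
        }
      gate <- check_luminal_attenuation(img, gate = config$gate)
      gate_value <- gate$value
      if (!gate$suitable) {
        abort_afd(sprintf("luminal attenuation %.0f <= gate %.0f",
                          gate$value, config$gate), "gate_failure")
      }
      seed_pt <- if (all(c("seed_x", "seed_y") %in% names(row)) &&
                     is.finite(row$seed_x) && is.finite(row$seed_y)) {
        c(row$seed_x, row$seed_y)
      } else NULL
      contour <- detect_border(img, lumen_seed = seed_pt,
                               threshold = config$threshold,
                               calcium_ceiling = config$calcium_ceiling)
      # out-of-range FD is an audit-log matter here, not a console warning:
      # fd and R^2 are recorded per image below
      fd_fit <- withCallingHandlers(
        compute_fd(contour, fdc),
        annulusFD_fd_out_of_range = function(w) invokeRestart("muffleWarning"))
      geom <- contour_measures(contour)
    }, annulusFD_error = function(e) {
      status <<- "excluded"
      reason <<- sub("^annulusFD_", "", class(e)[1])
      log_msg("EXCLUDE %s: %s", tag, conditionMessage(e))
    }, error = function(e) {
      status <<- "excluded"
      reason <<- "read_failure"
      log_msg("EXCLUDE %s: unreadable image (%s)", tag, conditionMessage(e))
    })
    if (status == "excluded") {
      n_excluded <- n_excluded + 1L
      res_rows[[i]] <- data.frame(
        subject_id = row$subject_id, plane = row$plane, phase = row$phase,
        status = status, reason = reason, gate_value = gate_value,
        fd = NA_real_, r_squared = NA_real_, area_mm2 = NA_real_,
        perimeter_mm = NA_real_, d_min_mm = NA_real_, d_max_mm = NA_real_,
        eccentricity_pct = NA_real_)
      next
    }
    log_msg("OK %s: gate %.0f, fd %.4f (R2 %.4f), area %.1f mm2",
            tag, gate_value, fd_fit$fd, fd_fit$r_squared, geom$area_mm2)
    res_rows[[i]] <- data.frame(
      subject_id = row$subject_id, plane = row$plane, phase = row$phase,
      status = status, reason = "", gate_value = gate_value,
      fd = fd_fit$fd, r_squared = fd_fit$r_squared,
      area_mm2 = geom$area_mm2, perimeter_mm = geom$perimeter_mm,
      d_min_mm = geom$d_min_mm, d_max_mm = geom$d_max_mm,
      eccentricity_pct = geom$eccentricity_pct)
    curve_rows[[length(curve_rows) + 1]] <- data.frame(
      subject_id = row$subject_id, plane = row$plane, phase = row$phase,
      caliber_mm = fd_fit$curve$caliber_mm,
      occupied_boxes = fd_fit$curve$occupied_boxes)
    sid <- as.character(row$subject_id)
    if (is.null(records[[sid]])) {
      records[[sid]] <- subject_record(
        sid,
        pvr_grade = if ("pvr_grade" %in% names(row)) row$pvr_grade
                    else NA_character_,
        composite_endpoint = if ("composite_endpoint" %in% names(row))
          row$composite_endpoint else NA)
    }
    records[[sid]]$fd[[cell]] <- fd_fit
    records[[sid]]$geometry[[cell]] <- geom
  }
  results <- do.call(rbind, res_rows)
  n_input <- nrow(manifest)
  n_analyzed <- n_input - n_excluded
  if (n_analyzed == 0) {
    abort_afd("all images were excluded; nothing to analyze", "all_unsuitable")
  }
  report <- NULL
  has_groups <- any(!is.na(vapply(records, record_group, logical(1),
                                  grouping = config$grouping)))
  if (has_groups) {
    report <- tryCatch(
      compare_cohort(unname(records), grouping = config$grouping,
                     target = config$target),
      annulusFD_insufficient_data = function(e) {
        log_msg("STATS skipped: %s", conditionMessage(e))
        NULL
      })
  }
  curves <- if (length(curve_rows)) do.call(rbind, curve_rows) else NULL
  write_csv_out(results, file.path(config$out_dir, "results.csv"))
  if (!is.null(curves)) {
    write_csv_out(curves, file.path(config$out_dir, "curves.csv"))
  }
  cfg <- unclass(config)
  jsonlite::write_json(cfg, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(report)) {
    jsonlite::write_json(
      list(grouping = report$grouping, target = report$target,
           table = report$table,
           roc = report$roc[c("auc", "ci_low", "ci_high", "cutoff",
                              "sensitivity", "specificity")]),
      file.path(config$out_dir, "stats.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  log_msg("SUMMARY input=%d analyzed=%d excluded=%d", n_input, n_analyzed,
          n_excluded)
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(list(results = results, curves = curves, report = report,
                 counts = c(input = n_input, analyzed = n_analyzed,
                            excluded = n_excluded),
                 out_dir = config$out_dir))
}

#' Generate and analyze a small demonstration cohort
#'
#' Renders a two-group cohort with a planted diastolic-annulus roughness
#' contrast (the positive group's border is rougher, so its FD is higher),
#' writes images and manifest under `out_dir`, runs the full pipeline on
#' them, and writes an `expected.json` sidecar stating the planted
#' statistical signature so test suites can assert against it. With
#' `null_demo = TRUE` both groups share the same roughness (a planted null).
#'
#' @param out_dir writable output directory.
#' @param seed integer seed.
#' @param n_per_group subjects per group.
#' @param null_demo plant no difference instead of the default contrast.
#' @return Invisibly, the [run_pipeline()] bundle with `manifest` and
#'   `expected` paths attached.
#' @export
make_demo <- function(out_dir, seed = 1, n_per_group = 10,
                      null_demo = FALSE) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort_afd(sprintf("cannot create output directory %s", out_dir),
              "io_error")
  }
  # the contrast is planted in the diastolic annulus cell only; all other
  # plane x phase cells share the negative group's roughness
  pos_by_cell <- if (null_demo) NULL else list("annulus.diastole" = 0.09)
  params <- list(
    negative = list(base_radius_mm = 12, roughness_amplitude = 0.03,
                    hurst_exponent = 0.4),
    positive = list(base_radius_mm = 12, roughness_amplitude = 0.03,
                    hurst_exponent = 0.4,
                    roughness_by_cell = pos_by_cell))
  labels <- list(
    negative = list(pvr_grade = "none", composite_endpoint = FALSE),
    positive = list(pvr_grade = "mild", composite_endpoint = TRUE))
  cohort <- generate_cohort(n_per_group, params, labels, seed = seed,
                            render = TRUE)
  manifest <- write_cohort(cohort, out_dir)
  config <- pipeline_config(compass_diameter_mm = 30, seed = seed,
                            out_dir = file.path(out_dir, "analysis"))
  bundle <- run_pipeline(manifest, config)
  expected <- list(
    planted_contrast = "annulus.diastole",
    null_demo = null_demo,
    direction = if (null_demo) "none" else "positive_group_higher_fd",
    expect_p_below = if (null_demo) NA else 0.05)
  jsonlite::write_json(expected, file.path(out_dir, "expected.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  bundle$manifest <- manifest
  bundle$expected <- file.path(out_dir, "expected.json")
  invisible(bundle)
}
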