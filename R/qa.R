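#' Run the full MVCT QA analysis
#'
#' Executes the four monthly QA image tests in order — geometric
#' distortion, uniformity, noise, contrast, resolution-plug localization —
#' on a DICOM series folder or an in-memory volume, grading against a
#' baseline when one is supplied. Marker detection is required by every
#' stage, so its failure aborts the run; any later stage error is recorded
#' on the report and the remaining independent stages still run.
#'
#' Without a baseline the geometric and contrast results are reported
#' ungraded ("baseline established") and the report can be exported as the
#' new baseline with [save_baseline()].
#'
#' @param input path to a DICOM series folder, or an [new_volume()] object.
#' @param baseline a [load_baseline()] record, a path to a baseline JSON
#'   file, or `NULL`.
#' @param config a [qa_config()].
#' @param resolution_grade optional `"pass"`/`"fail"` visual grade recorded
#'   on the result (see [record_visual_grade()]).
#' @return An object of class `qa_report`.
#' @export
run_qa <- function(input, baseline = NULL, config = qa_config(),
                   resolution_grade = NULL) {
  volume <- if (is.character(input)) read_series(input) else input
  stopifnot(inherits(volume, "mvct_volume"))
  if (is.character(baseline)) baseline <- load_baseline(baseline)

  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  markers <- tryCatch(
    detect_markers(volume, config$marker_threshold_hu, config$marker_area_px,
                   config$body_threshold_hu),
    error = function(e) {
      qa_abort(sprintf("marker detection failed (required by all stages): %s",
                       conditionMessage(e)), "stage_markers")
    }
  )

  geometric <- stage("geometric", {
    trans <- transaxial_distances(markers)
    d_bd <- longitudinal_distance(volume, markers, config$body_threshold_hu)
    measured <- stats::setNames(c(trans$distance_mm, as.numeric(d_bd)),
                                c(trans$label, "B-D"))
    base_geo <- if (!is.null(baseline)) baseline$geometric_mm
    geometric_test(measured, base_geo, config$mode)
  })
  uniformity <- stage("uniformity", uniformity_test(volume, markers, config))
  noise <- stage("noise", noise_test(volume, markers, config))

  contrast_measured <- stage("contrast", measure_contrast(volume, markers, config))
  contrast <- NULL
  if (!is.null(contrast_measured) && !is.null(baseline)) {
    contrast <- stage("contrast_grading", {
      measured <- stats::setNames(contrast_measured$mean_hu,
                                  contrast_measured$hole)
      base <- stats::setNames(baseline$contrast$hu, baseline$contrast$label)
      contrast_test(match_to_baseline(measured, base), config)
    })
  }

  resolution <- stage("resolution", resolution_test(volume, markers, config))
  if (!is.null(resolution) && !is.null(resolution_grade)) {
    resolution <- record_visual_grade(resolution, resolution_grade)
  }

  report <- structure(
    list(
      meta = list(
        n_slices = volume$meta$n_slices,
        pixel_spacing_mm = volume$meta$pixel_spacing_mm,
        slice_thickness_mm = volume$meta$slice_thickness_mm,
        series_uid = volume$meta$series_uid,
        machine_id = config$machine_id,
        package_version = as.character(utils::packageVersion("mvctqa")),
        format_version = config$format_version
      ),
      markers = markers,
      geometric = geometric,
      uniformity = uniformity,
      noise = noise,
      contrast_measured = contrast_measured,
      contrast = contrast,
      resolution = resolution,
      baseline = baseline,
      config_snapshot = config_snapshot(config),
      errors = errors
    ),
    class = "qa_report"
  )
  report$overall_status <- overall_status(report)
  report
}

# aggregate pass/fail/incomplete from the per-test results
overall_status <- function(report) {
  graded <- c(
    geometric = if (!is.null(report$geometric)) report$geometric$passed else NA,
    uniformity = if (!is.null(report$uniformity)) report$uniformity$passed else NA,
    contrast = if (!is.null(report$contrast)) report$contrast$all_passed else NA
  )
  res_grade <- if (!is.null(report$resolution)) report$resolution$visual_grade else "ungraded"
  if (any(graded %in% FALSE) || identical(res_grade, "fail")) return("fail")
  if (all(graded %in% TRUE) && identical(res_grade, "pass") &&
      length(report$errors) == 0L) {
    return("pass")
  }
  "incomplete"
}

#' @export
print.qa_report <- function(x, ...) {
  cat("<qa_report>  overall:", toupper(x$overall_status), "\n")
  if (!is.null(x$geometric)) {
    g <- x$geometric
    cat(sprintf("  geometric (%s, tol %.0f mm): %s\n", g$mode, g$tolerance_mm, g$status))
    print(g$table)
  }
  if (!is.null(x$uniformity)) {
    cat(sprintf("  uniformity: max |diff| %.2f HU (tol %.0f) -> %s\n",
                x$uniformity$max_abs_diff_hu, x$uniformity$tolerance_hu,
                if (x$uniformity$passed) "pass" else "fail"))
  }
  if (!is.null(x$noise)) {
    cat(sprintf("  noise: sigma %.2f HU (small ROI), %.2f HU (big ROI) [informational]\n",
                x$noise$sigma_small_hu, x$noise$sigma_big_hu))
  }
  if (!is.null(x$contrast)) {
    cat(sprintf("  contrast: %s\n", x$contrast$status))
  } else if (!is.null(x$contrast_measured)) {
    cat("  contrast: measured, no baseline\n")
  }
  if (!is.null(x$resolution)) {
    r <- x$resolution
    cat(sprintf("  resolution plug: offset %+d mm, hole %d (sigma %.1f HU); visual grade: %s\n",
                r$found_slice_offset_mm, r$hole_index, r$plug_sigma_hu, r$visual_grade))
  }
  for (nm in names(x$errors)) cat(sprintf("  [stage error] %s: %s\n", nm, x$errors[[nm]]))
  invisible(x)
}

# ---- baseline persistence ---------------------------------------------------

SUPPORTED_BASELINE_VERSIONS <- "1.0"

#' Save a QA result as the new baseline
#'
#' Persists the measured values of a report as a baseline record (JSON):
#' the four geometric distances, the uniformity difference, the two noise
#' sigmas (reference only) and the labelled contrast HU list, plus a
#' snapshot of the tolerances in force.
#'
#' @param report a [run_qa()] result with all stages measured.
#' @param path output JSON file.
#' @param acquisition_date optional ISO date string recorded on the
#'   baseline.
#' @return Invisibly, the baseline record (as [load_baseline()] returns).
#' @export
save_baseline <- function(report, path, acquisition_date = NULL) {
  stopifnot(inherits(report, "qa_report"))
  if (is.null(report$geometric) || is.null(report$uniformity) ||
      is.null(report$noise) || is.null(report$contrast_measured)) {
    qa_abort("report incomplete: all stages must be measured to save a baseline",
             "incomplete_baseline")
  }
  cm <- report$contrast_measured
  lab_map <- attr(cm, "labels")
  record <- list(
    format_version = SUPPORTED_BASELINE_VERSIONS[[1]],
    machine_id = report$meta$machine_id,
    acquisition_date = acquisition_date,
    geometric_mm = as.list(stats::setNames(report$geometric$table$measured_mm,
                                           report$geometric$table$label)),
    uniformity_hu = report$uniformity$max_abs_diff_hu,
    noise_hu = list(small = report$noise$sigma_small_hu,
                    big = report$noise$sigma_big_hu),
    contrast = data.frame(
      label = baseline_labels(cm$hole, report),
      hu = cm$mean_hu
    ),
    config = report$config_snapshot
  )
  # I(17) significant digits: doubles survive the decimal round-trip exactly
  jsonlite::write_json(record, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(as_baseline_record(record, path))
}

# labels come from the config's hole -> material map; unmapped holes get a
# positional label
baseline_labels <- function(holes, report) {
  map <- unlist(report$config_snapshot$plug_material_labels)
  hit <- match(as.character(holes), names(map))
  ifelse(is.na(hit), paste0("hole-", holes), unname(map[hit]))
}

as_baseline_record <- function(parsed, path) {
  structure(
    list(
      format_version = parsed$format_version,
      machine_id = parsed$machine_id,
      acquisition_date = parsed$acquisition_date,
      geometric_mm = unlist(parsed$geometric_mm),
      uniformity_hu = parsed$uniformity_hu,
      noise_hu = unlist(parsed$noise_hu),
      contrast = tibble::as_tibble(parsed$contrast),
      config = parsed$config,
      path = path
    ),
    class = "baseline_record"
  )
}

#' Load a baseline record
#'
#' @param path baseline JSON file written by [save_baseline()].
#' @return An object of class `baseline_record`.
#' @export
load_baseline <- function(path) {
  if (!file.exists(path)) {
    qa_abort(sprintf("baseline file '%s' does not exist", path), "io_error")
  }
  parsed <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) {
      qa_abort(sprintf("cannot parse baseline '%s': %s", path, conditionMessage(e)),
               "baseline_parse")
    }
  )
  if (is.null(parsed$format_version) ||
      !parsed$format_version %in% SUPPORTED_BASELINE_VERSIONS) {
    qa_abort(sprintf("unsupported baseline version '%s' in '%s'",
                     parsed$format_version %||% "<missing>", path),
             "baseline_version")
  }
  if (is.null(parsed$contrast) || NROW(parsed$contrast) < 1L) {
    qa_abort(sprintf("baseline '%s' has an empty contrast list", path),
             "baseline_parse")
  }
  as_baseline_record(parsed, path)
}

#' @export
print.baseline_record <- function(x, ...) {
  cat(sprintf("<baseline_record> %s (machine %s)\n",
              x$path %||% "", x$machine_id %||% "?"))
  cat("  geometric mm:", paste(sprintf("%s=%.2f", names(x$geometric_mm), x$geometric_mm),
                               collapse = ", "), "\n")
  cat(sprintf("  uniformity %.2f HU; noise %.2f/%.2f HU; %d contrast plugs\n",
              x$uniformity_hu, x$noise_hu[["small"]], x$noise_hu[["big"]],
              nrow(x$contrast)))
  invisible(x)
}
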