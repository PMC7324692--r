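#' QA report serialization and rendering
#'
#' The canonical machine-readable result is the JSON sidecar: it contains
#' every measured value, the baseline values and deviations, the per-item
#' grades, the tolerance snapshot and the stage errors, and it is
#' deterministic — two runs on the same data yield byte-identical files
#' (no wall-clock fields). The one-page PDF is a rendering of the same
#' content plus figure panels (marker overlay, ROI overlay, resolution
#' sub-image).
#'
#' @name qa_reporting
NULL

# plain-list view of a report, containing everything serializable
report_to_list <- function(report) {
  stopifnot(inherits(report, "qa_report"))
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  out <- list(
    format_version = report$meta$format_version,
    overall_status = report$overall_status,
    meta = report$meta,
    markers = list(
      centroids_mm = as.data.frame(report$markers$centroids_mm),
      middle_slice_index = report$markers$middle_slice_index,
      phantom_center_mm = as.numeric(report$markers$phantom_center_mm),
      component_areas_px = report$markers$component_areas_px
    ),
    geometric = if (!is.null(report$geometric)) list(
      table = as.data.frame(report$geometric$table),
      tolerance_mm = report$geometric$tolerance_mm,
      mode = report$geometric$mode,
      passed = report$geometric$passed,
      status = report$geometric$status
    ),
    uniformity = if (!is.null(report$uniformity)) list(
      table = as.data.frame(report$uniformity$table),
      max_abs_diff_hu = report$uniformity$max_abs_diff_hu,
      tolerance_hu = report$uniformity$tolerance_hu,
      passed = report$uniformity$passed,
      slice_index = report$uniformity$slice_index
    ),
    noise = if (!is.null(report$noise)) list(
      sigma_small_hu = report$noise$sigma_small_hu,
      sigma_big_hu = report$noise$sigma_big_hu,
      reference_band_hu = num(report$noise$reference_band_hu),
      informational = TRUE,
      slice_index = report$noise$slice_index
    ),
    contrast_measured = if (!is.null(report$contrast_measured)) list(
      table = as.data.frame(report$contrast_measured),
      slice_index = attr(report$contrast_measured, "slice_index"),
      rotation_deg = attr(report$contrast_measured, "rotation_deg")
    ),
    contrast = if (!is.null(report$contrast)) list(
      table = as.data.frame(report$contrast$table),
      all_passed = report$contrast$all_passed,
      status = report$contrast$status
    ),
    resolution = if (!is.null(report$resolution)) list(
      found_slice_offset_mm = report$resolution$found_slice_offset_mm,
      hole_index = report$resolution$hole_index,
      plug_sigma_hu = report$resolution$plug_sigma_hu,
      window_bounds_hu = num(report$resolution$window_bounds_hu),
      visual_grade = report$resolution$visual_grade,
      criterion_mm = report$resolution$criterion_mm
    ),
    baseline = if (!is.null(report$baseline)) list(
      machine_id = report$baseline$machine_id,
      acquisition_date = report$baseline$acquisition_date,
      geometric_mm = as.list(report$baseline$geometric_mm),
      uniformity_hu = report$baseline$uniformity_hu,
      noise_hu = as.list(report$baseline$noise_hu),
      contrast = as.data.frame(report$baseline$contrast)
    ),
    config = report$config_snapshot,
    errors = report$errors
  )
  out[!vapply(out, is.null, logical(1))]
}

#' Write the JSON sidecar for a report
#'
#' @param report a [run_qa()] result.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path,
                       auto_unbox = TRUE, digits = I(17), null = "null",
                       dataframe = "columns")
  invisible(path)
}

#' Read back a JSON sidecar
#'
#' @param path sidecar file written by [write_report_json()].
#' @return The parsed list.
#' @export
read_report_json <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

fmt_or <- function(x, fmt = "%.2f", none = "-") {
  if (is.null(x) || length(x) == 0L || all(is.na(x))) none else sprintf(fmt, x)
}

# text lines of the one-page report body
report_lines <- function(report) {
  l <- character(0)
  add <- function(...) l <<- c(l, sprintf(...))
  add("MVCT phantom image QA report")
  add("mvctqa %s | series %s | %d slices, %.3f mm px, %.1f mm slices | machine: %s",
      report$meta$package_version, report$meta$series_uid,
      report$meta$n_slices, report$meta$pixel_spacing_mm[1],
      report$meta$slice_thickness_mm, report$meta$machine_id)
  add("OVERALL: %s", toupper(report$overall_status))
  add("")
  if (!is.null(report$geometric)) {
    g <- report$geometric
    add("[Geometric distortion]  mode %s, tolerance %.0f mm -> %s",
        g$mode, g$tolerance_mm, toupper(g$status))
    for (i in seq_len(nrow(g$table))) {
      add("  %-4s measured %7.2f mm | baseline %s | deviation %s",
          g$table$label[i], g$table$measured_mm[i],
          fmt_or(g$table$baseline_mm[i], "%7.2f mm"),
          fmt_or(g$table$deviation_mm[i], "%+6.2f mm"))
    }
  }
  if (!is.null(report$uniformity)) {
    u <- report$uniformity
    add("[Uniformity]  slice %d, max |centre-periphery| %.2f HU (tolerance %.0f) -> %s",
        u$slice_index, u$max_abs_diff_hu, u$tolerance_hu,
        toupper(if (u$passed) "pass" else "fail"))
  }
  if (!is.null(report$noise)) {
    n <- report$noise
    add("[Noise]  sigma-CT %.2f HU (10 mm ROI), %.2f HU (big ROI); typical %g-%g HU [informational]",
        n$sigma_small_hu, n$sigma_big_hu,
        n$reference_band_hu[1], n$reference_band_hu[2])
    if (!is.null(report$baseline)) {
      add("  baseline (reference only): %.2f / %.2f HU",
          report$baseline$noise_hu[["small"]], report$baseline$noise_hu[["big"]])
    }
  }
  if (!is.null(report$contrast)) {
    ct <- report$contrast
    add("[Contrast]  %d plugs vs baseline -> %s", nrow(ct$table), toupper(ct$status))
    for (i in seq_len(nrow(ct$table))) {
      add("  hole %-2s -> %-13s measured %8.2f | baseline %8.2f | dev %+7.2f (tol %2.0f) %s",
          ct$table$measured_name[i], ct$table$baseline_name[i],
          ct$table$measured_hu[i], ct$table$baseline_hu[i],
          ct$table$deviation_hu[i], ct$table$tolerance_hu[i],
          ifelse(ct$table$passed[i], "pass", "FAIL"))
    }
  } else if (!is.null(report$contrast_measured)) {
    cm <- report$contrast_measured
    add("[Contrast]  measured, no baseline (baseline established)")
    for (i in seq_len(nrow(cm))) {
      add("  hole %-2d mean %8.2f HU (sigma %.2f, n=%d)",
          cm$hole[i], cm$mean_hu[i], cm$sigma_hu[i], cm$n_pixels[i])
    }
  }
  if (!is.null(report$resolution)) {
    r <- report$resolution
    add("[Spatial resolution]  plug at offset %+d mm, hole %d (sigma %.1f HU); window [%.0f, %.0f] HU",
        r$found_slice_offset_mm, r$hole_index, r$plug_sigma_hu,
        r$window_bounds_hu[1], r$window_bounds_hu[2])
    add("  criterion: %.1f mm holes visible; visual grade: %s",
        r$criterion_mm, toupper(r$visual_grade))
  }
  for (nm in names(report$errors)) add("[stage error] %s: %s", nm, report$errors[[nm]])
  l
}

#' Render the one-page PDF report (plus sidecar files)
#'
#' Writes `qa_report.pdf` (exactly one page: all measured values, baseline
#' values, deviations and grades, the tolerance snapshot, and three figure
#' panels), the canonical `qa_report.json` sidecar, and the resolution
#' sub-image as `resolution_plug.png`.
#'
#' @param report a [run_qa()] result; it should carry the analyzed volume
#'   as `volume` for the figure panels (set by [run_qa()] callers via
#'   `attach_volume`), otherwise panels are skipped.
#' @param out_dir output directory, created if needed.
#' @param volume optional [new_volume()] used for the figure panels.
#' @return Invisibly, a named list of the files written.
#' @export
render_report <- function(report, out_dir, volume = NULL) {
  stopifnot(inherits(report, "qa_report"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  pdf_path <- file.path(out_dir, "qa_report.pdf")
  json_path <- file.path(out_dir, "qa_report.json")
  png_path <- file.path(out_dir, "resolution_plug.png")

  write_report_json(report, json_path)

  panels <- list()
  if (!is.null(volume)) {
    panels <- tryCatch(list(
      markers = plot_markers(volume, report$markers),
      rois = plot_rois(volume, report$markers,
                       slice_index = report$uniformity$slice_index %||%
                         report$markers$middle_slice_index),
      resolution = if (!is.null(report$resolution)) plot_resolution(report$resolution)
    ), error = function(e) list())
  }

  grDevices::pdf(pdf_path, width = 8.27, height = 11.69, useDingbats = FALSE,
                 onefile = TRUE)
  on.exit(grDevices::dev.off(), add = TRUE)
  grid::grid.newpage()
  lines <- report_lines(report)
  # text block: top 65% of the page
  grid::pushViewport(grid::viewport(y = 1, height = grid::unit(0.66, "npc"),
                                    just = "top"))
  n <- length(lines)
  for (i in seq_len(n)) {
    bold <- i <= 3 || grepl("^\\[", lines[i])
    grid::grid.text(
      lines[i], x = grid::unit(0.03, "npc"),
      y = grid::unit(1 - (i - 0.8) / max(n + 1, 44), "npc"),
      just = c("left", "top"),
      gp = grid::gpar(fontfamily = "mono",
                      fontsize = if (i == 1) 13 else 8.2,
                      fontface = if (bold) "bold" else "plain")
    )
  }
  grid::popViewport()
  # figure panels: bottom third
  keep <- panels[!vapply(panels, is.null, logical(1))]
  if (length(keep) > 0) {
    for (k in seq_along(keep)) {
      grid::pushViewport(grid::viewport(
        x = (k - 0.5) / length(keep), y = 0.17,
        width = 1 / length(keep) - 0.02, height = 0.3
      ))
      print(keep[[k]], newpage = FALSE)
      grid::popViewport()
    }
  }

  files <- list(pdf = pdf_path, json = json_path)
  if (!is.null(report$resolution) && capabilities("png")) {
    img_plot <- plot_resolution(report$resolution)
    grDevices::png(png_path, width = 600, height = 600, res = 120)
    print(img_plot)
    grDevices::dev.off()
    files$png <- png_path
  }
  invisible(files)
}
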