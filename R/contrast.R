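#' Contrast (density-plug HU constancy) analysis
#'
#' Each inserted density plug's mean HU is measured in a 10 mm ROI at the
#' hole centre on the contrast slice (~50 mm from the middle toward the
#' plug side, which covers the liquid-type water container as well), then
#' matched to the nearest baseline HU irrespective of plug position, and
#' the deviation graded against a per-plug tolerance: 30 HU for water-like
#' materials, 50 HU otherwise, both user-overridable.
#'
#' @name contrast
NULL

#' Measure density-plug HU values
#'
#' @param volume an [new_volume()] object.
#' @param markers a [detect_markers()] result.
#' @param config a [qa_config()]. `config$selected_plugs` names the hole
#'   indices to measure (an open hole measures air); the hole layout is
#'   rotated by the phantom rotation detected from the marker
#'   constellation.
#' @return A tibble with one row per measured hole: `hole`, `x_mm`, `z_mm`,
#'   `mean_hu`, `sigma_hu`, `n_pixels`; attributes `slice_index`,
#'   `rotation_deg` and `side`.
#' @export
measure_contrast <- function(volume, markers, config = qa_config()) {
  dt <- volume$meta$slice_thickness_mm
  ns <- volume$meta$n_slices
  side <- config$contrast_direction
  if (identical(side, "auto")) {
    side <- detect_plug_side(volume, markers, config, config$contrast_offset_mm)
  }
  idx <- markers$middle_slice_index + side * round(config$contrast_offset_mm / dt)
  if (idx < 1L || idx > ns) {
    qa_abort("contrast slice out of scan range", "slice_out_of_range")
  }
  rot <- detect_rotation(markers, config$marker_layout)
  layout <- config$plug_layout
  xz <- rotate_xz(cbind(layout$x_mm, layout$z_mm), rot)
  sel <- match(config$selected_plugs, layout$hole)
  if (anyNA(sel)) qa_abort("selected_plugs not in plug layout", "bad_config")
  stats <- lapply(sel, function(h) {
    roi_stat(volume, idx, xz[h, ], config$roi_diameter_mm,
             origin_mm = markers$phantom_center_mm)
  })
  out <- dplyr::bind_cols(
    tibble::tibble(hole = layout$hole[sel], x_mm = xz[sel, 1], z_mm = xz[sel, 2]),
    dplyr::bind_rows(stats)
  )
  attr(out, "slice_index") <- as.integer(idx)
  attr(out, "rotation_deg") <- rot
  attr(out, "side") <- as.integer(side)
  out
}

#' Match measured plug HU values to baseline values
#'
#' One-to-one pairing minimizing the total absolute HU difference,
#' independent of plug position: both lists are ranked and paired rank by
#' rank, which attains the minimum-cost assignment for absolute differences
#' on a line. Ties are broken by ascending input index, so the pairing is
#' deterministic. Unequal lengths produce a partial matching (the ranks of
#' the shorter list) plus a warning.
#'
#' @param measured_hus numeric vector of measured plug means; names (e.g.
#'   hole indices) are carried through.
#' @param baseline_hus numeric vector of baseline HU values; names (e.g.
#'   material labels) are carried through.
#' @return A tibble with one row per pair: `measured_idx`, `baseline_idx`,
#'   `measured_name`, `baseline_name`, `measured_hu`, `baseline_hu`,
#'   `deviation_hu` (measured minus baseline), ordered by ascending
#'   measured index.
#' @export
match_to_baseline <- function(measured_hus, baseline_hus) {
  nm <- length(measured_hus)
  nb <- length(baseline_hus)
  if (nm != nb) {
    qa_warn(sprintf("unmatched plugs: %d measured vs %d baseline values", nm, nb),
            "unmatched_plugs")
  }
  k <- min(nm, nb)
  om <- order(measured_hus, seq_len(nm))[seq_len(k)]
  ob <- order(baseline_hus, seq_len(nb))[seq_len(k)]
  out <- tibble::tibble(
    measured_idx = om,
    baseline_idx = ob,
    measured_name = if (is.null(names(measured_hus))) as.character(om) else names(measured_hus)[om],
    baseline_name = if (is.null(names(baseline_hus))) as.character(ob) else names(baseline_hus)[ob],
    measured_hu = as.numeric(measured_hus[om]),
    baseline_hu = as.numeric(baseline_hus[ob]),
    deviation_hu = as.numeric(measured_hus[om]) - as.numeric(baseline_hus[ob])
  )
  dplyr::arrange(out, .data$measured_idx)
}

# default per-plug tolerance: water-like materials get the tighter limit
default_contrast_tolerance <- function(baseline_hu, tol = c(water_like = 30, other = 50)) {
  ifelse(abs(baseline_hu) <= 100, tol[["water_like"]], tol[["other"]])
}

#' Grade matched plug deviations
#'
#' Each matched pair is graded `|deviation| <= tolerance` (inclusive). The
#' default per-plug tolerance is 30 HU when the baseline value is
#' water-like (|HU| <= 100) and 50 HU otherwise;
#' `config$contrast_tolerance_overrides` (named by baseline label) replaces
#' individual tolerances.
#'
#' @param pairings a [match_to_baseline()] tibble.
#' @param config a [qa_config()].
#' @return An object of class `qa_contrast`: `table` (the pairings plus
#'   `tolerance_hu` and `passed`), `all_passed`, `status`.
#' @export
contrast_test <- function(pairings, config = qa_config()) {
  tol <- default_contrast_tolerance(pairings$baseline_hu, config$contrast_tolerance_hu)
  ov <- config$contrast_tolerance_overrides
  if (!is.null(ov)) {
    hit <- match(pairings$baseline_name, names(ov))
    tol[!is.na(hit)] <- as.numeric(ov[hit[!is.na(hit)]])
  }
  tab <- dplyr::mutate(pairings,
    tolerance_hu = tol,
    passed = abs(.data$deviation_hu) <= tol + 1e-9
  )
  structure(
    list(table = tab, all_passed = all(tab$passed),
         status = if (all(tab$passed)) "pass" else "fail"),
    class = "qa_contrast"
  )
}
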