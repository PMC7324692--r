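#' QA tolerance and parameter configuration
#'
#' All tolerances default to the TG-148-style recommended values and every
#' one of them can be overridden. Geometry parameters that the
#' recommendations leave open (periphery ROI distance, noise ROI size,
#' search ROI size) are explicit, documented defaults.
#'
#' @param mode `"srs"` (1 mm geometric tolerance) or `"non_srs"` (2 mm).
#' @param dose_calc_mode if `TRUE` the images feed dose calculation and the
#'   uniformity tolerance is 25 HU; otherwise 30 HU (the same reference
#'   used for the non-water contrast materials).
#' @param marker_threshold_hu,marker_area_px,body_threshold_hu marker
#'   binarization threshold, per-slice component area gate, and body-mask
#'   threshold.
#' @param roi_diameter_mm small-ROI diameter used for uniformity, noise and
#'   contrast (10 mm).
#' @param periphery_radius_mm distance from the phantom centre to the four
#'   cardinal periphery ROIs.
#' @param big_roi_diameter_mm big centre ROI for the noise test.
#' @param uniformity_tolerance_hu explicit override of the uniformity
#'   tolerance; `NULL` derives it from `dose_calc_mode`.
#' @param uniformity_offset_mm,contrast_offset_mm longitudinal offsets of
#'   the uniform (10 mm) and contrast (50 mm) slices from the middle slice.
#' @param uniformity_direction,contrast_direction `"auto"` (detect the plug
#'   side from the cross-section sigma) or +1/-1.
#' @param contrast_tolerance_hu named pair `c(water_like = , other = )`
#'   splitting the per-plug tolerance at |baseline| = 100 HU.
#' @param contrast_tolerance_overrides optional named numeric (names =
#'   baseline material labels) replacing individual plug tolerances.
#' @param selected_plugs hole indices measured in the contrast test.
#' @param plug_material_labels named character vector mapping hole index to
#'   material label, used when a new baseline is established.
#' @param noise_reference_band_hu typical MVCT noise band, printed for
#'   reference only.
#' @param resolution_roi_diameter_mm sigma-search ROI (14 mm: larger than
#'   the stat ROI, smaller than a hole pitch).
#' @param resolution_offsets_mm candidate plug offsets from the middle
#'   slice.
#' @param resolution_ambiguity relative sigma margin under which plug
#'   localization is declared ambiguous.
#' @param resolution_criterion_mm hole size that must be visible (1.6 mm).
#' @param resolution_hole_index,resolution_offset_mm manual override of the
#'   plug search.
#' @param marker_layout nominal marker positions (used for rotation
#'   detection).
#' @param plug_layout hole-centre layout tibble.
#' @param hole_diameter_mm plug-hole diameter.
#' @param machine_id free-text machine identifier recorded in baselines and
#'   reports.
#' @return An object of class `qa_config`.
#' @export
qa_config <- function(mode = c("non_srs", "srs"),
                      dose_calc_mode = TRUE,
                      marker_threshold_hu = 800,
                      marker_area_px = c(2, 200),
                      body_threshold_hu = -300,
                      roi_diameter_mm = 10,
                      periphery_radius_mm = 105,
                      big_roi_diameter_mm = 60,
                      uniformity_tolerance_hu = NULL,
                      uniformity_offset_mm = 10,
                      contrast_offset_mm = 50,
                      uniformity_direction = "auto",
                      contrast_direction = "auto",
                      contrast_tolerance_hu = c(water_like = 30, other = 50),
                      contrast_tolerance_overrides = NULL,
                      selected_plugs = 1:7,
                      plug_material_labels = stats::setNames(plug_materials()$material, 1:7),
                      noise_reference_band_hu = c(50, 70),
                      resolution_roi_diameter_mm = 14,
                      resolution_offsets_mm = c(35, -35, 90, -90),
                      resolution_ambiguity = 0.10,
                      resolution_criterion_mm = 1.6,
                      resolution_hole_index = NULL,
                      resolution_offset_mm = NULL,
                      marker_layout = default_marker_positions(3),
                      plug_layout = default_plug_layout(),
                      hole_diameter_mm = 25,
                      machine_id = "unspecified") {
  mode <- match.arg(mode)
  tol_pos <- c(uniformity_tolerance_hu, contrast_tolerance_hu,
               resolution_criterion_mm, roi_diameter_mm,
               periphery_radius_mm, big_roi_diameter_mm,
               resolution_roi_diameter_mm)
  if (any(tol_pos <= 0)) qa_abort("all tolerances and sizes must be > 0", "bad_config")
  structure(
    list(
      mode = mode, dose_calc_mode = dose_calc_mode,
      marker_threshold_hu = marker_threshold_hu,
      marker_area_px = marker_area_px,
      body_threshold_hu = body_threshold_hu,
      roi_diameter_mm = roi_diameter_mm,
      periphery_radius_mm = periphery_radius_mm,
      big_roi_diameter_mm = big_roi_diameter_mm,
      uniformity_tolerance_hu = uniformity_tolerance_hu,
      uniformity_offset_mm = uniformity_offset_mm,
      contrast_offset_mm = contrast_offset_mm,
      uniformity_direction = uniformity_direction,
      contrast_direction = contrast_direction,
      contrast_tolerance_hu = contrast_tolerance_hu,
      contrast_tolerance_overrides = contrast_tolerance_overrides,
      selected_plugs = selected_plugs,
      plug_material_labels = plug_material_labels,
      noise_reference_band_hu = noise_reference_band_hu,
      resolution_roi_diameter_mm = resolution_roi_diameter_mm,
      resolution_offsets_mm = resolution_offsets_mm,
      resolution_ambiguity = resolution_ambiguity,
      resolution_criterion_mm = resolution_criterion_mm,
      resolution_hole_index = resolution_hole_index,
      resolution_offset_mm = resolution_offset_mm,
      marker_layout = marker_layout,
      plug_layout = plug_layout,
      hole_diameter_mm = hole_diameter_mm,
      machine_id = machine_id,
      format_version = "1.0"
    ),
    class = "qa_config"
  )
}

# derived geometric tolerance in mm
geometric_tolerance_mm <- function(config) if (config$mode == "srs") 1 else 2

# config snapshot persisted into baselines and report sidecars
config_snapshot <- function(config) {
  list(
    mode = config$mode,
    dose_calc_mode = config$dose_calc_mode,
    geometric_tolerance_mm = geometric_tolerance_mm(config),
    uniformity_tolerance_hu = config$uniformity_tolerance_hu %||%
      (if (config$dose_calc_mode) 25 else 30),
    contrast_tolerance_hu = as.list(config$contrast_tolerance_hu),
    roi_diameter_mm = config$roi_diameter_mm,
    periphery_radius_mm = config$periphery_radius_mm,
    big_roi_diameter_mm = config$big_roi_diameter_mm,
    resolution_criterion_mm = config$resolution_criterion_mm,
    plug_material_labels = as.list(config$plug_material_labels),
    format_version = config$format_version
  )
}
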