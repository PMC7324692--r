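#' ROI statistics, uniformity and noise analysis
#'
#' Uniformity and noise are measured on the uniform slice 10 mm from the
#' phantom middle on the side away from the plug-bearing region: the HU
#' mean of a small (10 mm) centre ROI is compared with four cardinal
#' periphery ROIs, and the noise sigma-CT is the standard deviation in the
#' small and in a big (60 mm) centre ROI. Uniformity is graded against an
#' absolute tolerance; noise is informational and only displayed next to a
#' typical reference band.
#'
#' @name image_quality
NULL

#' Circular ROI statistics
#'
#' Membership is pixel-centre-in-circle, boundary inclusive; `sigma_hu` is
#' the sample standard deviation (n - 1 denominator).
#'
#' @param volume an [new_volume()] object.
#' @param slice_index transaxial slice to analyze.
#' @param center_mm (x, z) of the ROI centre in mm, relative to `origin_mm`.
#' @param diameter_mm ROI diameter in mm.
#' @param origin_mm (x, z) of the reference origin in image-centred mm
#'   coordinates; pass the detected phantom centre to express ROIs in the
#'   phantom frame.
#' @return A one-row tibble: `mean_hu`, `sigma_hu`, `n_pixels`.
#' @export
roi_stat <- function(volume, slice_index, center_mm, diameter_mm = 10,
                     origin_mm = c(0, 0)) {
  stopifnot(inherits(volume, "mvct_volume"), length(center_mm) == 2L)
  sl <- vol_slice(volume, slice_index)
  cx <- center_mm[1] + origin_mm[1]
  cz <- center_mm[2] + origin_mm[2]
  x <- vol_x_mm(volume)
  z <- vol_z_mm(volume)
  r2 <- (diameter_mm / 2)^2 + 1e-9
  cols <- which((x - cx)^2 <= r2)
  rows <- which((z - cz)^2 <= r2)
  if (length(cols) == 0L || length(rows) == 0L) {
    qa_abort("ROI too small: no pixel centres inside", "roi_too_small")
  }
  sub <- sl[rows, cols, drop = FALSE]
  inside <- outer((z[rows] - cz)^2, (x[cols] - cx)^2, `+`) <= r2
  vals <- sub[inside]
  if (length(vals) < 5L) {
    qa_abort(sprintf("ROI too small: %d pixel(s) inside", length(vals)), "roi_too_small")
  }
  tibble::tibble(
    mean_hu = mean(vals),
    sigma_hu = stats::sd(vals),
    n_pixels = length(vals)
  )
}

# whole-slice body-mask sigma, used to tell the plug-bearing side from the
# uniform side: plugs of different HU inflate the cross-sectional sigma
slice_body_sigma <- function(volume, slice_index, body_threshold_hu = -300) {
  sl <- vol_slice(volume, slice_index)
  stats::sd(sl[sl > body_threshold_hu])
}

# +1 if the plug-bearing region lies toward higher slice indices, else -1
detect_plug_side <- function(volume, markers, config, offset_mm = 50) {
  dt <- volume$meta$slice_thickness_mm
  off <- round(offset_mm / dt)
  ns <- volume$meta$n_slices
  cand <- markers$middle_slice_index + c(-off, off)
  ok <- cand >= 1L & cand <= ns
  if (!any(ok)) {
    qa_abort("both candidate slices out of scan range", "slice_out_of_range")
  }
  if (!all(ok)) return(if (ok[2]) 1L else -1L)
  sig <- vapply(cand, slice_body_sigma, numeric(1),
                volume = volume, body_threshold_hu = config$body_threshold_hu)
  if (sig[2] >= sig[1]) 1L else -1L
}

#' Select the uniform slice
#'
#' Returns the slice `10 mm` (`config$uniformity_offset_mm`) from the
#' middle of the phantom, on the side away from the plug-bearing region.
#' The plug side is auto-detected as the side with the larger body-mask
#' sigma at the contrast distance; `config$uniformity_direction` (+1/-1)
#' overrides the choice.
#'
#' @param volume an [new_volume()] object.
#' @param markers a [detect_markers()] result.
#' @param config a [qa_config()].
#' @return The slice index, with attribute `direction`.
#' @export
select_uniform_slice <- function(volume, markers, config = qa_config()) {
  dt <- volume$meta$slice_thickness_mm
  off <- round(config$uniformity_offset_mm / dt)
  ns <- volume$meta$n_slices
  dir <- config$uniformity_direction
  if (identical(dir, "auto")) {
    dir <- -detect_plug_side(volume, markers, config, config$contrast_offset_mm)
  }
  idx <- markers$middle_slice_index + dir * off
  if (idx < 1L || idx > ns) {
    alt <- markers$middle_slice_index - dir * off
    if (alt < 1L || alt > ns) {
      qa_abort("both candidate slices out of scan range", "slice_out_of_range")
    }
    qa_warn("preferred uniform slice out of range; using the other side",
            "uniform_slice_fallback")
    idx <- alt
    dir <- -dir
  }
  structure(as.integer(idx), direction = as.integer(dir))
}

#' Uniformity test
#'
#' Compares the mean HU of a centre ROI with four cardinal periphery ROIs
#' on the uniform slice; the largest absolute centre-periphery difference
#' is graded against the tolerance: 25 HU when the MVCT is used for dose
#' calculation, 30 HU for imaging-only use (configurable).
#'
#' @inheritParams select_uniform_slice
#' @return An object of class `qa_uniformity`: `table` (per-ROI stats),
#'   `max_abs_diff_hu`, `tolerance_hu`, `passed`, `slice_index`.
#' @export
uniformity_test <- function(volume, markers, config = qa_config()) {
  idx <- select_uniform_slice(volume, markers, config)
  r <- config$periphery_radius_mm
  centres <- rbind(
    center = c(0, 0),
    east = c(r, 0), north = c(0, r), west = c(-r, 0), south = c(0, -r)
  )
  # body radius from the maximum cross-section area
  area <- slice_area_above(volume, config$body_threshold_hu)
  body_r <- sqrt(max(area) / pi) * sqrt(prod(volume$meta$pixel_spacing_mm))
  if (r + config$roi_diameter_mm / 2 > body_r) {
    qa_abort(sprintf(
      "periphery ROI outside phantom: radius %.0f + ROI %.0f/2 exceeds body radius %.0f mm",
      r, config$roi_diameter_mm, body_r), "roi_outside_phantom")
  }
  stats <- lapply(seq_len(nrow(centres)), function(i) {
    roi_stat(volume, idx, centres[i, ], config$roi_diameter_mm,
             origin_mm = markers$phantom_center_mm)
  })
  tab <- dplyr::bind_cols(
    tibble::tibble(roi = rownames(centres),
                   x_mm = centres[, 1], z_mm = centres[, 2]),
    dplyr::bind_rows(stats)
  )
  diffs <- abs(tab$mean_hu[-1] - tab$mean_hu[1])
  tolerance <- config$uniformity_tolerance_hu %||%
    (if (config$dose_calc_mode) 25 else 30)
  max_diff <- max(diffs)
  structure(
    list(table = tab, max_abs_diff_hu = max_diff, tolerance_hu = tolerance,
         passed = max_diff <= tolerance + 1e-9, slice_index = as.integer(idx)),
    class = "qa_uniformity"
  )
}

#' Noise test
#'
#' The sigma-CT of the small (10 mm) and big (60 mm) centre ROIs on the
#' uniform slice. Noise is an inherent property of each image, so it is
#' never graded against baseline; the typical 50-70 HU band is shown for
#' reference only.
#'
#' @inheritParams select_uniform_slice
#' @return An object of class `qa_noise`: `sigma_small_hu`, `sigma_big_hu`,
#'   `reference_band_hu`, `informational` (always `TRUE`), `slice_index`.
#' @export
noise_test <- function(volume, markers, config = qa_config()) {
  idx <- select_uniform_slice(volume, markers, config)
  small <- roi_stat(volume, idx, c(0, 0), config$roi_diameter_mm,
                    origin_mm = markers$phantom_center_mm)
  big <- roi_stat(volume, idx, c(0, 0), config$big_roi_diameter_mm,
                  origin_mm = markers$phantom_center_mm)
  structure(
    list(sigma_small_hu = small$sigma_hu, sigma_big_hu = big$sigma_hu,
         n_small = small$n_pixels, n_big = big$n_pixels,
         reference_band_hu = config$noise_reference_band_hu,
         informational = TRUE, slice_index = as.integer(idx)),
    class = "qa_noise"
  )
}
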