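#' HU volume objects
#'
#' An `mvct_volume` is the substrate of every analysis: a 3D array of
#' Hounsfield units indexed `[slice, row, col]` plus the acquisition
#' geometry. The axis convention is fixed throughout the package:
#' the slice axis is the longitudinal (y) direction, the row axis is the
#' vertical (z) direction and the column axis is the lateral (x) direction.
#' In-plane coordinates are expressed in mm relative to the image centre
#' (or to the detected phantom centre where stated), with x increasing
#' with column index and z increasing with row index.
#'
#' @param hu 3D numeric array of Hounsfield units, `dim = c(slice, row, col)`.
#'   Values must be finite and lie in `[-1024, 4000]`.
#' @param pixel_spacing_mm length-2 positive numeric, (row, column) spacing in mm.
#' @param slice_thickness_mm positive scalar, slice spacing in mm.
#' @param rescale_slope,rescale_intercept calibration used when the volume was
#'   read from (or will be written to) DICOM stored pixel values.
#' @param series_uid opaque series identifier string.
#' @param validate check the HU invariants (finite, within `[-1024, 4000]`).
#'   Internal callers that construct values clamped by construction may skip
#'   the scan.
#'
#' @return An object of class `mvct_volume`: a list with elements `hu` and
#'   `meta` (`pixel_spacing_mm`, `slice_thickness_mm`, `n_slices`,
#'   `rescale_slope`, `rescale_intercept`, `series_uid`).
#' @export
new_volume <- function(hu, pixel_spacing_mm, slice_thickness_mm,
                       rescale_slope = 1, rescale_intercept = -1024,
                       series_uid = "", validate = TRUE) {
  if (!is.array(hu) || length(dim(hu)) != 3L) {
    qa_abort("`hu` must be a 3D array indexed (slice, row, col)", "bad_volume")
  }
  if (validate) {
    rng <- range(hu)   # NA/Inf propagate to the range
    if (!all(is.finite(rng))) {
      qa_abort("HU array contains non-finite values", "bad_volume")
    }
    if (rng[1] < -1024 || rng[2] > 4000) {
      qa_abort(
        sprintf("HU values outside [-1024, 4000] (range %.1f..%.1f)", rng[1], rng[2]),
        "bad_volume"
      )
    }
  }
  pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
  if (length(pixel_spacing_mm) == 1L) pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  stopifnot(length(pixel_spacing_mm) == 2L, all(pixel_spacing_mm > 0),
            is_number(slice_thickness_mm), slice_thickness_mm > 0)
  structure(
    list(
      hu = hu,
      meta = list(
        pixel_spacing_mm = pixel_spacing_mm,
        slice_thickness_mm = as.numeric(slice_thickness_mm),
        n_slices = dim(hu)[1L],
        rescale_slope = as.numeric(rescale_slope),
        rescale_intercept = as.numeric(rescale_intercept),
        series_uid = as.character(series_uid)
      )
    ),
    class = "mvct_volume"
  )
}

#' @export
print.mvct_volume <- function(x, ...) {
  d <- dim(x$hu)
  cat(sprintf(
    "<mvct_volume> %d slices x %d rows x %d cols | pixel %.3f x %.3f mm, slice %.2f mm\n",
    d[1], d[2], d[3],
    x$meta$pixel_spacing_mm[1], x$meta$pixel_spacing_mm[2],
    x$meta$slice_thickness_mm
  ))
  cat(sprintf("  HU range %.0f .. %.0f | series %s\n",
              min(x$hu), max(x$hu), x$meta$series_uid))
  invisible(x)
}

# in-plane pixel-centre coordinates (mm), relative to the image centre
vol_x_mm <- function(volume) {
  nc <- dim(volume$hu)[3L]
  (seq_len(nc) - (nc + 1) / 2) * volume$meta$pixel_spacing_mm[2L]
}

vol_z_mm <- function(volume) {
  nr <- dim(volume$hu)[2L]
  (seq_len(nr) - (nr + 1) / 2) * volume$meta$pixel_spacing_mm[1L]
}

# longitudinal slice-centre coordinates (mm), relative to the scan centre
vol_y_mm <- function(volume) {
  ns <- dim(volume$hu)[1L]
  (seq_len(ns) - (ns + 1) / 2) * volume$meta$slice_thickness_mm
}

# one transaxial slice as a row x col matrix
vol_slice <- function(volume, i) {
  ns <- dim(volume$hu)[1L]
  if (i < 1L || i > ns) {
    qa_abort(sprintf("slice index %d outside scan range 1..%d", i, ns),
             "slice_out_of_range")
  }
  volume$hu[i, , ]
}

# per-slice count of voxels above a HU threshold (fast path: the slice
# axis is the fastest-varying dimension, so a reshape gives slice rows)
slice_area_above <- function(volume, threshold_hu) {
  ns <- dim(volume$hu)[1L]
  rowSums(matrix(volume$hu > threshold_hu, nrow = ns))
}
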