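#' Figure panels for QA reports
#'
#' ggplot2 helpers used in the PDF report and available interactively.
#'
#' @name qa_plots
NULL

slice_df <- function(volume, slice_index, window = c(-1100, 1200)) {
  sl <- vol_slice(volume, slice_index)
  df <- expand.grid(z = vol_z_mm(volume), x = vol_x_mm(volume))
  df$hu <- pmin(pmax(as.vector(sl), window[1]), window[2])
  df
}

#' Plot one transaxial slice
#'
#' @param volume an [new_volume()] object.
#' @param slice_index slice to show.
#' @param window HU display window `c(low, high)`.
#' @return A ggplot.
#' @export
plot_slice <- function(volume, slice_index, window = c(-1100, 1200)) {
  df <- slice_df(volume, slice_index, window)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z, fill = .data$hu)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = window, name = "HU") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "z (mm)",
                  title = sprintf("slice %d", slice_index)) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(legend.position = "none")
}

circle_df <- function(cx, cz, r, id) {
  t <- seq(0, 2 * pi, length.out = 90)
  data.frame(x = cx + r * cos(t), z = cz + r * sin(t), id = id)
}

#' Marker-overlay panel
#'
#' Middle slice with the detected marker centroids marked.
#'
#' @param volume an [new_volume()] object.
#' @param markers a [detect_markers()] result.
#' @return A ggplot.
#' @export
plot_markers <- function(volume, markers) {
  ctr <- markers$phantom_center_mm
  pts <- data.frame(x = markers$centroids_mm[, 1] + ctr[1],
                    z = markers$centroids_mm[, 2] + ctr[2],
                    label = c("1", "2", "3"))
  plot_slice(volume, markers$middle_slice_index) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = .data$x, y = .data$z),
                        inherit.aes = FALSE,
                        shape = 3, colour = "red", size = 3, stroke = 1) +
    ggplot2::labs(title = sprintf("markers, slice %d", markers$middle_slice_index))
}

#' ROI-overlay panel
#'
#' A slice with the centre and periphery ROI circles drawn.
#'
#' @param volume an [new_volume()] object.
#' @param markers a [detect_markers()] result.
#' @param config a [qa_config()].
#' @param slice_index slice to show (defaults to the uniform slice).
#' @return A ggplot.
#' @export
plot_rois <- function(volume, markers, config = qa_config(), slice_index = NULL) {
  if (is.null(slice_index)) {
    slice_index <- as.integer(select_uniform_slice(volume, markers, config))
  }
  ctr <- markers$phantom_center_mm
  r <- config$periphery_radius_mm
  cs <- rbind(c(0, 0), c(r, 0), c(0, r), c(-r, 0), c(0, -r))
  circles <- do.call(rbind, lapply(seq_len(nrow(cs)), function(i) {
    circle_df(cs[i, 1] + ctr[1], cs[i, 2] + ctr[2], config$roi_diameter_mm / 2, i)
  }))
  circles <- rbind(circles, circle_df(ctr[1], ctr[2], config$big_roi_diameter_mm / 2, 6))
  plot_slice(volume, slice_index) +
    ggplot2::geom_path(data = circles,
                       ggplot2::aes(x = .data$x, y = .data$z, group = .data$id),
                       inherit.aes = FALSE, colour = "yellow", linewidth = 0.4) +
    ggplot2::labs(title = sprintf("ROIs, slice %d", slice_index))
}

#' Resolution sub-image panel
#'
#' The cropped resolution plug at its automatic window.
#'
#' @param resolution a `qa_resolution` object (from [resolution_test()]).
#' @return A ggplot.
#' @export
plot_resolution <- function(resolution) {
  stopifnot(inherits(resolution, "qa_resolution"))
  win <- resolution$window
  df <- expand.grid(z = win$z_mm, x = win$x_mm)
  b <- win$window_bounds_hu
  df$hu <- pmin(pmax(as.vector(win$image), b[1]), b[2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z, fill = .data$hu)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = b, name = "HU") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "x (mm)", y = "z (mm)",
      title = sprintf("resolution plug, slice %d [%.0f, %.0f] HU",
                      win$slice_index, b[1], b[2])
    ) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(legend.position = "none")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Panel overview of a QA report
#'
#' @param object a `qa_report` (the analyzed volume must be supplied).
#' @param volume the analyzed [new_volume()].
#' @param ... unused.
#' @return A ggplot (patchwork when available).
#' @export
autoplot.qa_report <- function(object, volume, ...) {
  p1 <- plot_markers(volume, object$markers)
  p2 <- plot_rois(volume, object$markers,
                  slice_index = object$uniformity$slice_index %||% NULL)
  p3 <- if (!is.null(object$resolution)) plot_resolution(object$resolution)
  if (requireNamespace("patchwork", quietly = TRUE) && !is.null(p3)) {
    p1 + p2 + p3
  } else {
    p1
  }
}
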