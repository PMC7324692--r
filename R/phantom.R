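#' Density-plug materials and reference HU values
#'
#' The seven vendor density plugs routinely used for the MVCT contrast
#' constancy test, with reference mega-voltage HU values used as the
#' generator defaults (machine-acceptance baseline scale).
#'
#' @return A tibble with columns `material` and `hu`.
#' @export
plug_materials <- function() {
  tibble::tibble(
    material = c("LN-300", "LN-450", "Water", "Inner bone",
                 "CB2-30%", "CB2-50%", "Cortical bone"),
    hu = c(-685.70, -515.72, -1.12, 97.95, 269.95, 467.28, 668.27)
  )
}

#' Default fiducial marker layout
#'
#' Three (optionally four) marker positions in the phantom mid-plane, in mm
#' relative to the cylinder axis. The triangle side lengths are fixed at
#' 101.0, 147.7 and 226.4 mm (the machine-acceptance transaxial baseline);
#' the absolute angular placement is not standardized, so the triangle is
#' centred on the axis with one side horizontal — a documented package
#' constant. The optional fourth marker (the TomoTherapy-style phantom has
#' one more than the Radixact-style) sits near the centre so that the
#' three-marker rule always recovers the calibrated triangle.
#'
#' @param n_markers 3 or 4.
#' @return An `n x 2` matrix of (x, z) mm.
#' @export
default_marker_positions <- function(n_markers = 3) {
  stopifnot(n_markers %in% c(3, 4))
  ab <- 101.0; bc <- 147.7; ca <- 226.4
  a <- c(0, 0)
  b <- c(ab, 0)
  cx <- (ca^2 + ab^2 - bc^2) / (2 * ab)
  cz <- sqrt(ca^2 - cx^2)
  pts <- rbind(a, b, c(cx, cz))
  pts <- sweep(pts, 2, colMeans(pts))  # centre triangle on the axis
  if (n_markers == 4) pts <- rbind(pts, c(0, 20))
  dimnames(pts) <- NULL
  pts
}

#' Default plug-hole layout
#'
#' Twenty holes on two concentric rings: 12 on an outer ring (r = 115 mm,
#' every 30 degrees) and 8 on an inner ring (r = 65 mm, every 45 degrees).
#' The hole count matches the phantom; the exact hole coordinates of the
#' commercial phantom are not published, so the rings are a documented,
#' configurable package constant.
#'
#' @return A tibble with columns `hole`, `x_mm`, `z_mm`, `ring`, `angle_deg`.
#' @export
default_plug_layout <- function() {
  outer_a <- seq(0, 330, by = 30)
  inner_a <- seq(0, 315, by = 45)
  tibble::tibble(
    hole = 1:20,
    ring = c(rep("outer", 12), rep("inner", 8)),
    radius_mm = c(rep(115, 12), rep(65, 8)),
    angle_deg = c(outer_a, inner_a),
    x_mm = radius_mm * cospi(angle_deg / 180),
    z_mm = radius_mm * sinpi(angle_deg / 180)
  )
}

default_plug_contents <- function() {
  m <- plug_materials()
  contents <- as.list(m$hu)
  names(contents) <- as.character(1:7)
  contents[["8"]] <- "air"
  contents[["9"]] <- "resolution"
  contents
}

#' Specify a synthetic cheese phantom
#'
#' Describes a virtual cylindrical water-equivalent phantom (30 cm diameter,
#' 18 cm long) in air, with high-HU fiducial markers in the mid-plane,
#' 20 peripheral plug holes, an optional high-texture resolution plug, plus
#' the acquisition geometry and noise of an MVCT fine-mode scan. All
#' defaults are the routine QA conditions: 1 mm slices, 0.762 mm pixels,
#' the seven density plugs at their reference HU values, one hole open to
#' air, and the resolution plug 35 mm from the mid-plane.
#'
#' @param diameter_mm,length_mm cylinder dimensions.
#' @param body_hu,background_hu,marker_hu material HU values.
#' @param marker_diameter_mm,marker_length_mm fiducial size (transaxial
#'   diameter; longitudinal extent).
#' @param marker_positions `n x 2` matrix of mid-plane (x, z) positions, 3 or
#'   4 rows.
#' @param marker_y_offset_mm longitudinal offset of the marker plane from
#'   the phantom middle (0 in the physical phantom; nonzero values make
#'   translation fixtures).
#' @param plug_layout tibble of hole centres, see [default_plug_layout()].
#' @param hole_diameter_mm plug-hole diameter.
#' @param plug_contents named list mapping hole index (as character) to a
#'   plug HU value, `"air"` (open hole) or `"resolution"`.
#' @param plug_span_mm length-2 vector: longitudinal extent of the inserted
#'   density plugs, in mm from the mid-plane toward `plug_side`. The hole
#'   bottoms end about 30 mm from the middle, plugs extend from there to the
#'   phantom end, so the contrast slice 50 mm out intersects every plug.
#' @param plug_side +1 or -1: the end the density plugs are loaded from.
#' @param resolution_plug_offset_mm centre of the resolution-plug hole
#'   pattern: +-35 or +-90 mm from the mid-plane depending on insertion
#'   direction and depth.
#' @param resolution_jitter_hu half-width of the uniform per-voxel HU
#'   jitter that models the plug's drilled texture.
#' @param noise_sigma_hu Gaussian image-noise sigma.
#' @param rotation_deg in-plane phantom rotation, one of 0/90/180/270.
#' @param scale_error length-2 (x, z) multiplicative geometric-error factors.
#' @param phantom_shift_mm longitudinal shift of the whole phantom in the
#'   scan field of view.
#' @param pixel_spacing_mm,slice_thickness_mm,fov_mm,scan_margin_mm
#'   acquisition sampling; the scan covers the phantom length plus margin
#'   of air at both ends (220 slices at the defaults).
#' @param seed integer RNG seed; identical specs and seeds give identical
#'   volumes.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(diameter_mm = 300, length_mm = 180,
                         body_hu = 0, background_hu = -1024, marker_hu = 1100,
                         marker_diameter_mm = 6, marker_length_mm = 3,
                         marker_positions = default_marker_positions(3),
                         marker_y_offset_mm = 0,
                         plug_layout = default_plug_layout(),
                         hole_diameter_mm = 25,
                         plug_contents = default_plug_contents(),
                         plug_span_mm = c(30, 90), plug_side = 1,
                         resolution_plug_offset_mm = 35,
                         resolution_jitter_hu = 300,
                         noise_sigma_hu = 20,
                         rotation_deg = 0, scale_error = c(1, 1),
                         phantom_shift_mm = 0,
                         pixel_spacing_mm = 0.762, slice_thickness_mm = 1,
                         fov_mm = 340, scan_margin_mm = 20,
                         seed = 1) {
  marker_positions <- matrix(marker_positions, ncol = 2L)
  if (!nrow(marker_positions) %in% c(3L, 4L)) {
    qa_abort("marker count must be 3 or 4", "bad_spec")
  }
  if (any(sqrt(rowSums(marker_positions^2)) >= diameter_mm / 2)) {
    qa_abort("marker positions outside the cylinder", "bad_spec")
  }
  if (any(sqrt(plug_layout$x_mm^2 + plug_layout$z_mm^2) +
          hole_diameter_mm / 2 > diameter_mm / 2)) {
    qa_abort("plug holes outside the cylinder", "bad_spec")
  }
  if (!is.null(plug_contents) && anyDuplicated(names(plug_contents))) {
    qa_abort("layout conflict: hole assigned more than one plug", "layout_conflict")
  }
  stopifnot(noise_sigma_hu >= 0, rotation_deg %in% c(0, 90, 180, 270),
            plug_side %in% c(-1, 1),
            resolution_plug_offset_mm %in% c(35, -35, 90, -90))
  if (length(scale_error) == 1L) scale_error <- rep(scale_error, 2L)
  structure(
    list(
      diameter_mm = diameter_mm, length_mm = length_mm,
      body_hu = body_hu, background_hu = background_hu, marker_hu = marker_hu,
      marker_diameter_mm = marker_diameter_mm, marker_length_mm = marker_length_mm,
      marker_positions = marker_positions, marker_y_offset_mm = marker_y_offset_mm,
      plug_layout = plug_layout, hole_diameter_mm = hole_diameter_mm,
      plug_contents = plug_contents,
      plug_span_mm = plug_span_mm, plug_side = plug_side,
      resolution_plug_offset_mm = resolution_plug_offset_mm,
      resolution_jitter_hu = resolution_jitter_hu,
      noise_sigma_hu = noise_sigma_hu,
      rotation_deg = rotation_deg, scale_error = as.numeric(scale_error),
      phantom_shift_mm = phantom_shift_mm,
      pixel_spacing_mm = pixel_spacing_mm, slice_thickness_mm = slice_thickness_mm,
      fov_mm = fov_mm, scan_margin_mm = scan_margin_mm,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

# structure coordinates as placed in the image: rotation, then scanner
# scale error
transform_xz <- function(xz, spec) {
  out <- rotate_xz(xz, spec$rotation_deg)
  out[, 1] <- out[, 1] * spec$scale_error[1]
  out[, 2] <- out[, 2] * spec$scale_error[2]
  out
}

# drilled hole-pattern offsets for the resolution plug: 7 groups (0.8-2.0 mm
# hole diameters) on a ring inside the plug, 3 holes per group
resolution_pattern <- function() {
  d <- c(0.8, 1.0, 1.2, 1.4, 1.6, 1.8, 2.0)
  out <- list()
  for (k in seq_along(d)) {
    ang <- 2 * pi * (k - 1) / 7
    centre <- 7 * c(cos(ang), sin(ang))
    for (j in -1:1) {
      out[[length(out) + 1L]] <- c(centre + j * 2.2 * d[k] * c(-sin(ang), cos(ang)),
                                   d[k] / 2)
    }
  }
  do.call(rbind, out)  # columns: dx, dz, radius
}

#' Generate a synthetic phantom volume with ground truth
#'
#' Renders the phantom described by a [phantom_spec()] into an HU volume.
#' A voxel takes a structure's HU if its centre lies inside the structure
#' (no antialiasing), Gaussian noise of `noise_sigma_hu` is added
#' everywhere, and the result is quantized to integer HU as in any CT
#' reconstruction. The returned ground truth is derived analytically from
#' the spec before noise.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` (an [new_volume()] object) and
#'   `truth`: marker positions and sorted pairwise distances (mm), the
#'   middle-slice index, the marker-to-nearest-end distance, the per-hole
#'   plug HU map and the resolution-plug location.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dx <- spec$pixel_spacing_mm
  dt <- spec$slice_thickness_mm
  n_px <- round(spec$fov_mm / dx)
  ns <- round((spec$length_mm + 2 * spec$scan_margin_mm) / dt)
  eps <- 1e-9

  x <- (seq_len(n_px) - (n_px + 1) / 2) * dx   # column coordinate
  z <- (seq_len(n_px) - (n_px + 1) / 2) * dx   # row coordinate
  X <- matrix(x, n_px, n_px, byrow = TRUE)
  Z <- matrix(z, n_px, n_px)
  y <- (seq_len(ns) - (ns + 1) / 2) * dt

  body_idx <- which(X^2 + Z^2 <= (spec$diameter_mm / 2)^2 + eps)

  markers <- transform_xz(spec$marker_positions, spec)
  marker_idx <- lapply(seq_len(nrow(markers)), function(k) {
    which((X - markers[k, 1])^2 + (Z - markers[k, 2])^2 <=
            (spec$marker_diameter_mm / 2)^2 + eps)
  })

  holes <- spec$plug_layout
  hole_xz <- transform_xz(cbind(holes$x_mm, holes$z_mm), spec)
  contents <- spec$plug_contents %||% list()
  occupied <- as.integer(names(contents))
  if (any(is.na(occupied)) || any(!occupied %in% holes$hole)) {
    qa_abort("plug_contents names must be hole indices 1..20", "bad_spec")
  }
  hole_idx <- lapply(seq_along(occupied), function(k) {
    h <- match(occupied[k], holes$hole)
    which((X - hole_xz[h, 1])^2 + (Z - hole_xz[h, 2])^2 <=
            (spec$hole_diameter_mm / 2)^2 + eps)
  })

  res_hole <- occupied[vapply(contents, identical, logical(1), "resolution")]
  res_idx <- NULL
  res_drill_idx <- NULL
  if (length(res_hole) == 1L) {
    h <- match(res_hole, holes$hole)
    centre <- hole_xz[h, ]
    res_idx <- hole_idx[[match(res_hole, occupied)]]
    pat <- resolution_pattern()
    pat_xz <- rotate_xz(pat[, 1:2], spec$rotation_deg)
    res_drill_idx <- unlist(lapply(seq_len(nrow(pat)), function(k) {
      which((X - centre[1] - pat_xz[k, 1])^2 + (Z - centre[2] - pat_xz[k, 2])^2 <=
              pat[k, 3]^2 + eps)
    }))
  } else if (length(res_hole) > 1L) {
    qa_abort("layout conflict: resolution plug assigned to several holes",
             "layout_conflict")
  }

  y0 <- spec$phantom_shift_mm                   # phantom centre in scan
  marker_y <- y0 + spec$marker_y_offset_mm      # marker plane
  half_len <- spec$length_mm / 2
  span <- sort(spec$plug_side * spec$plug_span_mm) + y0
  res_off <- spec$resolution_plug_offset_mm

  set.seed(spec$seed)
  # Most slices share one of a handful of noiseless structure templates
  # (air, body, body+plugs, body+markers, ...); resolution-plug slices get
  # per-slice templates because their texture jitter is an independent draw.
  # The compiled kernel then adds noise, rounds and clamps in one pass.
  templates <- list()
  tpl_key <- character(0)
  slice_map <- integer(ns)
  for (i in seq_len(ns)) {
    yy <- y[i]
    in_phantom <- abs(yy - y0) <= half_len + eps
    in_plug_span <- in_phantom && yy >= span[1] - eps && yy <= span[2] + eps
    in_res <- in_phantom && !is.null(res_idx) && abs(yy - (y0 + res_off)) <= 10 + eps
    in_marker <- in_phantom && abs(yy - marker_y) <= spec$marker_length_mm / 2 + eps
    key <- if (in_res) sprintf("res%d", i) else {
      paste(in_phantom, in_plug_span, in_marker)
    }
    k <- match(key, tpl_key)
    if (is.na(k)) {
      sl <- matrix(spec$background_hu, n_px, n_px)
      if (in_phantom) {
        sl[body_idx] <- spec$body_hu
        if (in_plug_span) {
          for (j in seq_along(occupied)) {
            val <- contents[[j]]
            if (identical(val, "resolution")) next
            sl[hole_idx[[j]]] <- if (identical(val, "air")) spec$background_hu else as.numeric(val)
          }
        }
        if (in_res) {
          sl[res_idx] <- 100 +
            stats::runif(length(res_idx), -spec$resolution_jitter_hu,
                         spec$resolution_jitter_hu)
          sl[res_drill_idx] <- spec$background_hu
        }
        if (in_marker) {
          for (j in seq_along(marker_idx)) sl[marker_idx[[j]]] <- spec$marker_hu
        }
      }
      templates[[length(templates) + 1L]] <- sl
      tpl_key <- c(tpl_key, key)
      k <- length(templates)
    }
    slice_map[i] <- k
  }
  hu <- finalize_volume(templates, slice_map, spec$noise_sigma_hu, n_px, n_px)
  dim(hu) <- c(ns, n_px, n_px)

  volume <- new_volume(hu, pixel_spacing_mm = dx, slice_thickness_mm = dt,
                       validate = FALSE)

  kept <- best_three(markers)
  pd <- sort(stats::dist(markers[kept, ]))
  marker_slices <- which(abs(y - marker_y) <= spec$marker_length_mm / 2 + eps)
  truth <- list(
    marker_positions_mm = markers,
    kept_markers = kept,
    pairwise_distances_mm = as.numeric(pd),
    middle_slice_index = round_half_up(mean(marker_slices)),
    middle_slice_frac = mean(marker_slices),
    d_bd_mm = half_len - abs(spec$marker_y_offset_mm),
    plug_positions_mm = tibble::tibble(
      hole = holes$hole, x_mm = hole_xz[, 1], z_mm = hole_xz[, 2]
    ),
    plug_hu_map = tibble::tibble(
      hole = occupied,
      content = vapply(contents, function(v) {
        if (is.character(v)) v else "density"
      }, character(1)),
      hu = vapply(contents, function(v) {
        if (is.character(v)) NA_real_ else as.numeric(v)
      }, numeric(1))
    ),
    resolution_plug = if (length(res_hole) == 1L) {
      list(offset_mm = res_off, hole_index = as.integer(res_hole))
    },
    rotation_deg = spec$rotation_deg
  )
  list(volume = volume, truth = truth)
}

# indices of the 3 markers with maximal pairwise-distance sum
best_three <- function(pts) {
  n <- nrow(pts)
  if (n == 3L) return(1:3)
  combos <- utils::combn(n, 3L)
  sums <- apply(combos, 2, function(ix) sum(stats::dist(pts[ix, ])))
  combos[, which.max(sums)]
}

#' Inject an in-plane geometric scaling error into a volume
#'
#' Resamples every slice with per-axis magnification about the image
#' centre (nearest-neighbour), so that marker separations scale by the
#' given factors within voxel quantization. A factor of exactly 1 returns
#' the input unchanged. Used as a negative-control fixture for the
#' geometric-distortion tolerance.
#'
#' @param volume an [new_volume()] object.
#' @param scale_error length-2 (x, z) factors, each in (0.9, 1.1).
#' @return A new volume of the same dimensions.
#' @export
inject_distortion <- function(volume, scale_error) {
  if (length(scale_error) == 1L) scale_error <- rep(scale_error, 2L)
  stopifnot(all(scale_error > 0.9), all(scale_error < 1.1))
  if (all(scale_error == 1)) return(volume)
  d <- dim(volume$hu)
  nr <- d[2L]; nc <- d[3L]
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  rmap <- round((seq_len(nr) - cr) / scale_error[2] + cr)
  cmap <- round((seq_len(nc) - cc) / scale_error[1] + cc)
  rok <- rmap >= 1 & rmap <= nr
  cok <- cmap >= 1 & cmap <= nc
  hu <- array(-1024, dim = d)
  for (i in seq_len(d[1L])) {
    sl <- matrix(-1024, nr, nc)
    sl[rok, cok] <- volume$hu[i, rmap[rok], cmap[cok]]
    hu[i, , ] <- sl
  }
  out <- new_volume(hu, volume$meta$pixel_spacing_mm, volume$meta$slice_thickness_mm,
                    volume$meta$rescale_slope, volume$meta$rescale_intercept,
                    volume$meta$series_uid)
  out
}
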