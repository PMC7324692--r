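#' Fiducial marker detection and geometric distortion analysis
#'
#' The geometric consistency test binarizes the volume at a high HU
#' threshold, finds the fiducial marker blobs, measures the three transaxial
#' centroid-to-centroid distances and the longitudinal marker-to-surface
#' distance, and grades the deviations from baseline against the 1 mm
#' (SRS/SBRT) or 2 mm tolerance.
#'
#' @name phantom_geometry
NULL

# 8-connected component labels for a sparse pixel set (one slice)
label_components_8 <- function(rows, cols) {
  n <- length(rows)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  key <- rows * 1e5 + cols
  offsets <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1))
  for (k in seq_len(nrow(offsets))) {
    nb <- (rows + offsets[k, 1]) * 1e5 + (cols + offsets[k, 2])
    j <- match(nb, key)
    hit <- which(!is.na(j))
    for (i in hit) {
      ri <- find(i); rj <- find(j[i])
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Detect the fiducial markers
#'
#' Binarizes the volume at `threshold_hu`, labels 2D 8-connected components
#' per slice, gates them by pixel area, and clusters components across
#' adjacent slices into physical markers. Each marker centroid is the
#' unweighted mean of its member pixel centres, converted to mm and
#' expressed relative to the phantom centre (the body-mask centroid on the
#' middle slice). Exactly three markers are returned: when four qualify,
#' the three with maximal pairwise-distance sum are kept (ties broken by
#' larger area, then scan order), so both phantom versions are analyzed
#' identically.
#'
#' @param volume an [new_volume()] object.
#' @param threshold_hu binarization threshold; the default 800 HU sits well
#'   above every body/plug material and below the marker HU, with margin
#'   for partial-volume dilution.
#' @param area_limits_px length-2 integer: per-slice component pixel-area
#'   gate rejecting noise speckle (below) and non-marker structures (above).
#' @param body_threshold_hu threshold of the phantom body mask used to
#'   locate the phantom centre.
#' @return An object of class `marker_set`: `centroids_mm` (3 x 2, (x, z)
#'   relative to the phantom centre), `middle_slice_index`,
#'   `middle_slice_frac`, `component_areas_px`, `phantom_center_mm`,
#'   `n_candidates`.
#' @export
detect_markers <- function(volume, threshold_hu = 800, area_limits_px = c(2, 200),
                           body_threshold_hu = -300) {
  stopifnot(inherits(volume, "mvct_volume"))
  hits <- which(volume$hu > threshold_hu, arr.ind = TRUE)
  if (nrow(hits) == 0L) {
    qa_abort("markers not found: no voxels above threshold", "markers_not_found")
  }
  dx_col <- volume$meta$pixel_spacing_mm[2L]
  dx_row <- volume$meta$pixel_spacing_mm[1L]

  comp <- list()
  for (s in sort(unique(hits[, 1L]))) {
    sel <- hits[, 1L] == s
    rows <- hits[sel, 2L]; cols <- hits[sel, 3L]
    labels <- label_components_8(rows, cols)
    for (lab in unique(labels)) {
      m <- labels == lab
      area <- sum(m)
      if (area < area_limits_px[1] || area > area_limits_px[2]) next
      comp[[length(comp) + 1L]] <- c(
        slice = s, area = area,
        sum_row = sum(rows[m]), sum_col = sum(cols[m])
      )
    }
  }
  if (length(comp) == 0L) {
    qa_abort("markers not found: no components within area limits", "markers_not_found")
  }
  comp <- do.call(rbind, comp)
  cx <- comp[, "sum_col"] / comp[, "area"] * dx_col
  cz <- comp[, "sum_row"] / comp[, "area"] * dx_row

  # cluster per-slice components into physical markers by in-plane proximity
  cluster_r <- 15  # mm; markers are > 100 mm apart
  cl <- integer(nrow(comp))
  centres <- list()
  for (i in seq_len(nrow(comp))) {
    assigned <- FALSE
    for (k in seq_along(centres)) {
      if ((cx[i] - centres[[k]][1])^2 + (cz[i] - centres[[k]][2])^2 < cluster_r^2) {
        cl[i] <- k; assigned <- TRUE; break
      }
    }
    if (!assigned) {
      centres[[length(centres) + 1L]] <- c(cx[i], cz[i])
      cl[i] <- length(centres)
    }
  }

  agg <- lapply(seq_along(centres), function(k) {
    m <- cl == k
    area <- sum(comp[m, "area"])
    c(area = area,
      x = sum(comp[m, "sum_col"]) / area * dx_col,
      z = sum(comp[m, "sum_row"]) / area * dx_row,
      slice = sum(comp[m, "slice"] * comp[m, "area"]) / area)
  })
  agg <- do.call(rbind, agg)

  n <- nrow(agg)
  if (n < 3L) {
    qa_abort(sprintf("markers not found: only %d marker candidate(s)", n),
             "markers_not_found")
  }
  if (n > 4L) {
    qa_abort(
      sprintf("ambiguous markers: %d candidates at (x, z) mm: %s", n,
              paste(sprintf("(%.1f, %.1f)", agg[, "x"], agg[, "z"]), collapse = " ")),
      "ambiguous_markers"
    )
  }
  if (n == 4L) {
    pts <- agg[, c("x", "z")]
    combos <- utils::combn(4L, 3L)
    sums <- apply(combos, 2, function(ix) sum(stats::dist(pts[ix, ])))
    best <- which(abs(sums - max(sums)) < 1e-9)
    if (length(best) > 1L) {
      areas <- apply(combos[, best, drop = FALSE], 2, function(ix) sum(agg[ix, "area"]))
      best <- best[order(-areas, best)][1L]
    }
    keep <- combos[, best[1L]]
  } else {
    keep <- 1:3
  }
  kept <- agg[keep, , drop = FALSE]

  middle_frac <- sum(kept[, "slice"] * kept[, "area"]) / sum(kept[, "area"])
  middle <- as.integer(round_half_up(middle_frac))

  # phantom centre: body-mask centroid on the middle slice
  sl <- vol_slice(volume, middle)
  body <- sl > body_threshold_hu
  xs <- vol_x_mm(volume); zs <- vol_z_mm(volume)
  npx <- sum(body)
  centre <- c(
    x = sum(matrix(xs, nrow(sl), ncol(sl), byrow = TRUE)[body]) / npx,
    z = sum(matrix(zs, nrow(sl), ncol(sl))[body]) / npx
  )
  # centroids were computed in pixel units from the image corner; re-express
  # them in the centred mm frame before subtracting the phantom centre
  x0 <- (ncol(sl) + 1) / 2 * dx_col
  z0 <- (nrow(sl) + 1) / 2 * dx_row
  centroids <- cbind(x = kept[, "x"] - x0 - centre["x"],
                     z = kept[, "z"] - z0 - centre["z"])
  rownames(centroids) <- NULL

  structure(
    list(
      centroids_mm = centroids,
      middle_slice_index = middle,
      middle_slice_frac = middle_frac,
      component_areas_px = as.integer(kept[, "area"]),
      phantom_center_mm = unname(centre),
      n_candidates = n
    ),
    class = "marker_set"
  )
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> middle slice %d (%.2f); phantom centre (%.1f, %.1f) mm\n",
              x$middle_slice_index, x$middle_slice_frac,
              x$phantom_center_mm[1], x$phantom_center_mm[2]))
  for (i in 1:3) {
    cat(sprintf("  marker %d: (%7.2f, %7.2f) mm, %d px\n", i,
                x$centroids_mm[i, 1], x$centroids_mm[i, 2], x$component_areas_px[i]))
  }
  invisible(x)
}

#' Transaxial marker distances
#'
#' The three pairwise centroid distances, reported in ascending order and
#' labelled A-B < B-C < C-A by length, so the labelling is invariant under
#' phantom rotation and marker relabelling (vertex B is the endpoint shared
#' by the two shortest edges).
#'
#' @param markers a [detect_markers()] result.
#' @return A tibble with columns `label` and `distance_mm` (ascending).
#' @export
transaxial_distances <- function(markers) {
  stopifnot(inherits(markers, "marker_set"))
  d <- as.numeric(stats::dist(markers$centroids_mm))
  if (min(d) < 1) {
    qa_abort("degenerate marker pair: two centroids nearly coincide", "degenerate_markers")
  }
  tibble::tibble(label = c("A-B", "B-C", "C-A"), distance_mm = sort(d))
}

#' Longitudinal marker-to-surface distance
#'
#' The phantom end surfaces are found from the per-slice body-mask area:
#' a slice is inside the phantom when its area is at least half the maximum
#' cross-section. The surface position is the outer edge of the outermost
#' such slice (slice centre plus half a slice thickness). The distance is
#' measured from the fractional marker plane (the area-weighted mean marker
#' slice position) to the nearest end surface contained in the scan.
#'
#' @param volume an [new_volume()] object.
#' @param markers a [detect_markers()] result.
#' @param body_threshold_hu body-mask threshold (default -300 HU).
#' @return The distance in mm, with attribute `end` (`"low"` or `"high"`).
#' @export
longitudinal_distance <- function(volume, markers, body_threshold_hu = -300) {
  stopifnot(inherits(volume, "mvct_volume"), inherits(markers, "marker_set"))
  area <- slice_area_above(volume, body_threshold_hu)
  in_mask <- area >= 0.5 * max(area)
  first <- which(in_mask)[1L]
  last <- rev(which(in_mask))[1L]
  ns <- volume$meta$n_slices
  contained <- c(low = first > 1L, high = last < ns)
  if (!any(contained)) {
    qa_abort("surface not in scan: phantom truncated on both ends", "surface_not_in_scan")
  }
  y <- vol_y_mm(volume)
  dt <- volume$meta$slice_thickness_mm
  marker_y <- (markers$middle_slice_frac - (ns + 1) / 2) * dt
  dists <- c(low = abs((y[first] - dt / 2) - marker_y),
             high = abs((y[last] + dt / 2) - marker_y))
  dists[!contained] <- Inf
  end <- names(which.min(dists))
  structure(unname(dists[end]), end = end)
}

#' Grade geometric distortion against baseline
#'
#' Deviations are measured minus baseline per matched label and graded
#' against the mode tolerance: 1 mm for SRS/SBRT, 2 mm otherwise. The
#' comparison is inclusive — a deviation of exactly the tolerance passes.
#' Without a baseline the distances are reported ungraded so they can be
#' saved as the new baseline.
#'
#' @param measured,baseline named numeric vectors in mm with names
#'   `A-B`, `B-C`, `C-A`, `B-D`. `baseline` may be `NULL`.
#' @param mode `"srs"` or `"non_srs"`.
#' @return An object of class `qa_geometric` with a `table` tibble
#'   (`label`, `measured_mm`, `baseline_mm`, `deviation_mm`), the tolerance,
#'   `passed` (logical, `NA` when no baseline) and a status string.
#' @export
geometric_test <- function(measured, baseline = NULL, mode = c("non_srs", "srs")) {
  mode <- match.arg(mode)
  labels <- c("A-B", "B-C", "C-A", "B-D")
  if (!all(labels %in% names(measured))) {
    qa_abort("measured distances must be named A-B, B-C, C-A, B-D", "bad_input")
  }
  measured <- measured[labels]
  tolerance <- if (mode == "srs") 1 else 2
  if (is.null(baseline)) {
    tab <- tibble::tibble(
      label = labels, measured_mm = as.numeric(measured),
      baseline_mm = NA_real_, deviation_mm = NA_real_
    )
    return(structure(
      list(table = tab, tolerance_mm = tolerance, mode = mode,
           passed = NA, status = "baseline established"),
      class = "qa_geometric"
    ))
  }
  if (!all(labels %in% names(baseline))) {
    qa_abort("incomparable baseline: labels do not match A-B, B-C, C-A, B-D",
             "incomparable_baseline")
  }
  baseline <- baseline[labels]
  dev <- as.numeric(measured) - as.numeric(baseline)
  passed <- all(abs(dev) <= tolerance + 1e-9)
  tab <- tibble::tibble(
    label = labels, measured_mm = as.numeric(measured),
    baseline_mm = as.numeric(baseline), deviation_mm = dev
  )
  structure(
    list(table = tab, tolerance_mm = tolerance, mode = mode,
         passed = passed, status = if (passed) "pass" else "fail"),
    class = "qa_geometric"
  )
}

#' Detect the phantom rotation from the marker constellation
#'
#' Matches the detected marker centroids to the nominal marker layout under
#' each of the four cardinal rotations and returns the rotation with the
#' smallest total assignment distance. Works for both the 3- and 4-marker
#' layouts because the calibrated triangle is scalene.
#'
#' @param markers a [detect_markers()] result.
#' @param nominal_positions `n x 2` matrix of nominal (x, z) marker
#'   positions (mm, phantom frame).
#' @return One of 0, 90, 180, 270 (degrees).
#' @export
detect_rotation <- function(markers, nominal_positions = default_marker_positions(3)) {
  pts <- markers$centroids_mm
  nominal_positions <- matrix(nominal_positions, ncol = 2L)
  n <- nrow(nominal_positions)
  maps <- expand.grid(rep(list(seq_len(n)), 3L))
  maps <- maps[apply(maps, 1, function(r) !anyDuplicated(r)), , drop = FALSE]
  best_rot <- 0; best_cost <- Inf
  for (rot in c(0, 90, 180, 270)) {
    nom <- rotate_xz(nominal_positions, rot)
    costs <- apply(maps, 1, function(ix) {
      sum(sqrt(rowSums((pts - nom[ix, , drop = FALSE])^2)))
    })
    if (min(costs) < best_cost) {
      best_cost <- min(costs)
      best_rot <- rot
    }
  }
  best_rot
}
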