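# Shared fixtures, generated once per test session and cached.
# Grids are chosen so the whole suite stays fast; the acceptance file works
# at the sizes stated there.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# standard mid-resolution phantom: all structures present
std_phantom <- function() {
  fixture("std", generate_phantom(
    phantom_spec(pixel_spacing_mm = 1.5, fov_mm = 300, seed = 11)
  ))
}

# full-resolution phantom (0.762 mm pixels), for pixel-count-sensitive checks
fine_phantom <- function() {
  fixture("fine", generate_phantom(phantom_spec(seed = 4)))
}

# noiseless phantom without plugs or markers
flat_phantom <- function() {
  fixture("flat", generate_phantom(
    phantom_spec(noise_sigma_hu = 0, plug_contents = NULL,
                 marker_hu = 0, pixel_spacing_mm = 2, slice_thickness_mm = 2,
                 fov_mm = 320, seed = 1)
  ))
}

std_markers <- function() {
  fixture("std_markers", detect_markers(std_phantom()$volume))
}

# independent brute-force ROI oracle: naive per-pixel double loop
roi_stat_bruteforce <- function(volume, slice_index, center_mm, diameter_mm,
                                origin_mm = c(0, 0)) {
  sl <- volume$hu[slice_index, , ]
  nr <- nrow(sl); nc <- ncol(sl)
  dx <- volume$meta$pixel_spacing_mm[2L]
  dz <- volume$meta$pixel_spacing_mm[1L]
  cx <- center_mm[1] + origin_mm[1]
  cz <- center_mm[2] + origin_mm[2]
  r2 <- (diameter_mm / 2)^2 + 1e-9
  vals <- c()
  for (r in seq_len(nr)) {
    for (co in seq_len(nc)) {
      x <- (co - (nc + 1) / 2) * dx
      z <- (r - (nr + 1) / 2) * dz
      if ((x - cx)^2 + (z - cz)^2 <= r2) vals <- c(vals, sl[r, co])
    }
  }
  list(mean = mean(vals), sigma = sd(vals), n = length(vals))
}

# exhaustive minimum-cost one-to-one assignment oracle (n <= 7)
match_bruteforce <- function(measured, baseline) {
  n <- length(measured)
  stopifnot(length(baseline) == n, n <= 7)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cost <- sum(abs(measured - baseline[p]))
    if (cost < best_cost - 1e-12) {
      best_cost <- cost
      best <- p
    }
  }
  list(assignment = best, cost = best_cost)
}

# fabricated marker_set for pure-geometry tests
fake_marker_set <- function(centroids, middle = 100, frac = middle) {
  structure(
    list(centroids_mm = matrix(centroids, ncol = 2L),
         middle_slice_index = middle, middle_slice_frac = frac,
         component_areas_px = rep(10L, 3L),
         phantom_center_mm = c(0, 0), n_candidates = 3L),
    class = "marker_set"
  )
}

# reference transaxial baseline (machine-acceptance values, mm)
baseline_triple_mm <- c(101.0, 147.7, 226.4)
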