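# marker detection and geometric distortion grading

test_that("marker centroids match ground truth within half a pixel", {
  g <- std_phantom()
  m <- std_markers()
  px <- g$volume$meta$pixel_spacing_mm[1]
  truth <- g$truth$marker_positions_mm[g$truth$kept_markers, ]
  err <- apply(truth, 1, function(p) {
    min(sqrt(rowSums(sweep(m$centroids_mm, 2, p)^2)))
  })
  expect_true(all(err <= 0.5 * px))
  expect_equal(m$middle_slice_index, g$truth$middle_slice_index)
})

test_that("detection is rotation invariant on the sorted distance triple", {
  base <- transaxial_distances(std_markers())$distance_mm
  px <- 2
  for (rot in c(90, 180, 270)) {
    g <- generate_phantom(phantom_spec(
      rotation_deg = rot, pixel_spacing_mm = px, slice_thickness_mm = 2,
      fov_mm = 300, seed = 11
    ))
    d <- transaxial_distances(detect_markers(g$volume))$distance_mm
    expect_true(all(abs(d - baseline_triple_mm) <= 0.5 * px + 0.1))
  }
})

test_that("a fourth marker is dropped keeping the calibrated triangle", {
  g4 <- fixture("four_marker", generate_phantom(phantom_spec(
    marker_positions = default_marker_positions(4),
    pixel_spacing_mm = 2, slice_thickness_mm = 2, fov_mm = 300, seed = 2
  )))
  m <- detect_markers(g4$volume)
  expect_equal(m$n_candidates, 4L)
  expect_equal(nrow(m$centroids_mm), 3L)
  d <- transaxial_distances(m)$distance_mm
  expect_true(all(abs(d - baseline_triple_mm) <= 1.1))
})

test_that("marker detection errors are informative", {
  g <- flat_phantom()   # marker_hu = 0: nothing above threshold
  expect_error(detect_markers(g$volume), "markers not found")
  # fewer than 3 markers
  g2 <- fixture("two_marker", generate_phantom(phantom_spec(
    marker_positions = default_marker_positions(3),
    marker_hu = 1100, pixel_spacing_mm = 2, slice_thickness_mm = 2,
    fov_mm = 240, scan_margin_mm = 4, plug_contents = NULL, seed = 3
  )))
  # raise the area gate so all components are rejected
  expect_error(detect_markers(g2$volume, area_limits_px = c(500, 600)),
               "markers not found")
})

test_that("transaxial distances are ascending, labelled, and Euclidean", {
  m <- fake_marker_set(rbind(c(0, 0), c(101, 0), c(101, 147.7)))
  d <- transaxial_distances(m)
  expect_equal(d$label, c("A-B", "B-C", "C-A"))
  expect_equal(d$distance_mm,
               sort(c(101, 147.7, sqrt(101^2 + 147.7^2))), tolerance = 1e-12)
  # coincident centroids are degenerate
  m2 <- fake_marker_set(rbind(c(0, 0), c(0.1, 0), c(100, 100)))
  expect_error(transaxial_distances(m2), "degenerate marker pair")
})

test_that("longitudinal distance follows the phantom ends", {
  g <- std_phantom()
  m <- std_markers()
  d <- longitudinal_distance(g$volume, m)
  expect_equal(as.numeric(d), 90, tolerance = 1e-9)

  # marker plane moved 5 mm toward one end changes d_bd by exactly 5 mm
  gs <- fixture("shifted", generate_phantom(phantom_spec(
    marker_y_offset_mm = 5, pixel_spacing_mm = 2, slice_thickness_mm = 1,
    fov_mm = 240, scan_margin_mm = 10, plug_contents = NULL,
    noise_sigma_hu = 0, seed = 1
  )))
  ms <- detect_markers(gs$volume)
  ds <- longitudinal_distance(gs$volume, ms)
  expect_equal(as.numeric(ds), 85, tolerance = 1e-9)

  # phantom filling the whole scan has no surface in range
  gt <- fixture("truncated", generate_phantom(phantom_spec(
    pixel_spacing_mm = 2, slice_thickness_mm = 2, fov_mm = 240,
    scan_margin_mm = 0, plug_contents = NULL, noise_sigma_hu = 0, seed = 1
  )))
  mt <- detect_markers(gt$volume)
  expect_error(longitudinal_distance(gt$volume, mt), "surface not in scan")
})

test_that("geometric grading is inclusive and mode dependent", {
  base <- c("A-B" = 101.0, "B-C" = 147.7, "C-A" = 226.4, "B-D" = 89.0)

  # measured equals baseline: zero deviations, pass
  r0 <- geometric_test(base, base, mode = "srs")
  expect_true(r0$passed)
  expect_true(all(r0$table$deviation_mm == 0))

  # a 0.3 mm deviation passes the 1 mm SRS tolerance
  meas <- base + c(0.3, -0.1, 0.2, 0)
  expect_true(geometric_test(meas, base, mode = "srs")$passed)

  # exactly 1.0 mm passes (inclusive); 1.01 mm fails in SRS but passes non-SRS
  meas2 <- base; meas2["B-D"] <- base["B-D"] + 1.0
  expect_true(geometric_test(meas2, base, mode = "srs")$passed)
  meas3 <- base; meas3["B-D"] <- base["B-D"] + 1.01
  expect_false(geometric_test(meas3, base, mode = "srs")$passed)
  expect_true(geometric_test(meas3, base, mode = "non_srs")$passed)

  # no baseline: ungraded, marked as new baseline
  rn <- geometric_test(base, NULL, mode = "srs")
  expect_identical(rn$status, "baseline established")
  expect_true(is.na(rn$passed))

  # mismatched labels are incomparable
  bad <- stats::setNames(base, c("A-B", "B-C", "C-A", "X-Y"))
  expect_error(geometric_test(base, bad), "incomparable baseline")
})

test_that("rotation detection recovers the phantom orientation", {
  for (rot in c(0, 90, 180, 270)) {
    g <- generate_phantom(phantom_spec(
      rotation_deg = rot, pixel_spacing_mm = 2, slice_thickness_mm = 2,
      fov_mm = 300, seed = 11
    ))
    m <- detect_markers(g$volume)
    expect_equal(detect_rotation(m), rot)
  }
})
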