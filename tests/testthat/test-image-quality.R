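# ROI statistics, uniformity, noise, contrast

test_that("roi_stat agrees with the brute-force pixel loop", {
  g <- std_phantom()
  m <- std_markers()
  idx <- m$middle_slice_index - 7
  set.seed(99)
  for (i in 1:12) {
    ctr <- runif(2, -80, 80)
    dia <- runif(1, 8, 20)
    fast <- roi_stat(g$volume, idx, ctr, dia, origin_mm = m$phantom_center_mm)
    slow <- roi_stat_bruteforce(g$volume, idx, ctr, dia,
                                origin_mm = m$phantom_center_mm)
    expect_equal(fast$mean_hu, slow$mean, tolerance = 1e-9)
    expect_equal(fast$sigma_hu, slow$sigma, tolerance = 1e-9)
    expect_identical(fast$n_pixels, slow$n)
  }
})

test_that("roi_stat handles constant fields and tiny ROIs", {
  g <- flat_phantom()
  mid <- g$truth$middle_slice_index
  s <- roi_stat(g$volume, mid, c(0, 0), 10)
  expect_equal(s$mean_hu, 0)
  expect_equal(s$sigma_hu, 0)
  expect_error(roi_stat(g$volume, mid, c(0, 0), 0.5), "ROI too small")
})

test_that("sigma estimates track the generator noise", {
  g <- std_phantom()   # sigma 20, 1.5 mm pixels
  m <- std_markers()
  idx <- as.integer(select_uniform_slice(g$volume, m))
  small <- roi_stat(g$volume, idx, c(0, 0), 10, origin_mm = m$phantom_center_mm)
  big <- roi_stat(g$volume, idx, c(0, 0), 60, origin_mm = m$phantom_center_mm)
  expect_lt(abs(small$sigma_hu - 20) / 20, 0.15)
  expect_lt(abs(big$sigma_hu - 20) / 20, 0.05)
})

test_that("uniform slice selection goes away from the plug side", {
  g <- std_phantom()   # plugs toward +y
  m <- std_markers()
  idx <- select_uniform_slice(g$volume, m)
  off <- round(10 / g$volume$meta$slice_thickness_mm)
  expect_equal(attr(idx, "direction"), -1L)
  expect_equal(as.integer(idx), m$middle_slice_index - off)

  # 2 mm slices give a 5-slice offset
  g2 <- fixture("coarse2", generate_phantom(phantom_spec(
    pixel_spacing_mm = 2, slice_thickness_mm = 2, fov_mm = 300, seed = 11
  )))
  m2 <- detect_markers(g2$volume)
  idx2 <- select_uniform_slice(g2$volume, m2)
  expect_equal(abs(as.integer(idx2) - m2$middle_slice_index), 5L)
})

test_that("uniformity is graded against the absolute tolerance", {
  g <- std_phantom()
  m <- std_markers()
  u <- uniformity_test(g$volume, m, qa_config())
  expect_equal(nrow(u$table), 5L)
  expect_equal(u$tolerance_hu, 25)
  expect_equal(u$max_abs_diff_hu,
               max(abs(u$table$mean_hu[-1] - u$table$mean_hu[1])))
  expect_true(u$passed)   # clean phantom is uniform

  # noiseless phantom: difference exactly zero
  gf <- flat_phantom()
  mf <- fake_marker_set(default_marker_positions(3),
                        middle = gf$truth$middle_slice_index)
  uf <- uniformity_test(gf$volume, mf, qa_config())
  expect_equal(uf$max_abs_diff_hu, 0)

  # a +30 HU biased periphery region fails the 25 HU dose-calculation
  # tolerance (injected into the noiseless phantom so the difference is
  # exactly 30)
  vb <- gf$volume
  x <- mvctqa:::vol_x_mm(vb)
  z <- mvctqa:::vol_z_mm(vb)
  idxb <- as.integer(select_uniform_slice(vb, mf, qa_config(uniformity_direction = -1)))
  east <- outer(z^2, (x - 105)^2, `+`) <= 12^2
  sl <- vb$hu[idxb, , ]
  sl[east] <- sl[east] + 30
  vb$hu[idxb, , ] <- sl
  ub <- uniformity_test(vb, mf, qa_config(uniformity_direction = -1))
  expect_equal(ub$max_abs_diff_hu, 30)
  expect_false(ub$passed)

  # periphery ROI beyond the body is rejected
  expect_error(uniformity_test(g$volume, m, qa_config(periphery_radius_mm = 160)),
               "outside phantom")
})

test_that("uniformity difference is shift invariant; sigma is shift invariant and gain equivariant", {
  g <- std_phantom()
  m <- std_markers()
  u1 <- uniformity_test(g$volume, m, qa_config())
  v2 <- g$volume
  v2$hu <- v2$hu + 7
  u2 <- uniformity_test(v2, m, qa_config())
  expect_equal(u2$max_abs_diff_hu, u1$max_abs_diff_hu, tolerance = 1e-9)

  idx <- as.integer(select_uniform_slice(g$volume, m))
  s1 <- roi_stat(g$volume, idx, c(0, 0), 20, origin_mm = m$phantom_center_mm)
  s2 <- roi_stat(v2, idx, c(0, 0), 20, origin_mm = m$phantom_center_mm)
  expect_equal(s2$sigma_hu, s1$sigma_hu, tolerance = 1e-9)
  v3 <- g$volume
  v3$hu <- v3$hu * 1.5
  s3 <- roi_stat(v3, idx, c(0, 0), 20, origin_mm = m$phantom_center_mm)
  expect_equal(s3$sigma_hu, 1.5 * s1$sigma_hu, tolerance = 1e-9)
})

test_that("noise test is informational with small and big ROI sigmas", {
  g <- std_phantom()
  m <- std_markers()
  n <- noise_test(g$volume, m, qa_config())
  expect_true(n$informational)
  expect_equal(n$reference_band_hu, c(50, 70))
  expect_gt(n$n_big, n$n_small)

  gf <- flat_phantom()
  mf <- fake_marker_set(default_marker_positions(3),
                        middle = gf$truth$middle_slice_index)
  nf <- noise_test(gf$volume, mf, qa_config())
  expect_equal(nf$sigma_small_hu, 0)
  expect_equal(nf$sigma_big_hu, 0)
})

test_that("contrast measurement recovers the generated plug HUs", {
  g <- std_phantom()
  m <- std_markers()
  cm <- measure_contrast(g$volume, m, qa_config())
  expect_equal(cm$hole, 1:7)
  truth <- plug_materials()$hu
  # noise sigma 20, n ~ 30 px at 1.5 mm pixels (+/- 0.3 HU quantization)
  tol <- 3 * 20 / sqrt(cm$n_pixels) + 0.3
  expect_true(all(abs(cm$mean_hu - truth) <= tol))

  # the open hole measures air
  cm_air <- measure_contrast(g$volume, m, qa_config(selected_plugs = 8))
  expect_equal(cm_air$mean_hu, -1024, tolerance = 15)
})

test_that("noiseless plugs measure exactly their generated HU", {
  gn <- fixture("noiseless_plugs", generate_phantom(phantom_spec(
    noise_sigma_hu = 0, pixel_spacing_mm = 2, slice_thickness_mm = 2,
    fov_mm = 300, plug_contents = list(`1` = -700, `4` = 100, `13` = 500),
    seed = 1
  )))
  mn <- detect_markers(gn$volume)
  cm <- measure_contrast(gn$volume, mn, qa_config(selected_plugs = c(1, 4, 13)))
  expect_equal(cm$mean_hu, c(-700, 100, 500))
})

test_that("nearest-HU matching equals the exhaustive minimum-cost assignment", {
  # identity on equal lists
  base <- stats::setNames(plug_materials()$hu, plug_materials()$material)
  p0 <- match_to_baseline(base, base)
  expect_true(all(p0$deviation_hu == 0))
  expect_equal(p0$measured_idx, p0$baseline_idx)

  # permutation of the measured list gives the same pairs (position independence)
  set.seed(3)
  perm <- sample(7)
  p1 <- match_to_baseline(base[perm], base)
  expect_equal(sort(p1$deviation_hu), rep(0, 7))
  expect_equal(p1$baseline_name[order(p1$measured_hu)],
               names(base)[order(base)])

  # measured values from a post-detector-replacement QA pair with their
  # same-material baseline under the minimum total |difference|
  qa3 <- c(-703.38, -538.26, -41.84, 61.51, 227.09, 409.13, 614.14)
  p2 <- match_to_baseline(qa3, base)
  oracle <- match_bruteforce(qa3[order(qa3)], as.numeric(base)[order(base)])
  expect_equal(sum(abs(p2$deviation_hu)), oracle$cost, tolerance = 1e-9)
  expect_equal(p2$baseline_name, names(base))   # identity by material

  # random instances against the exhaustive oracle
  for (s in 1:6) {
    set.seed(s)
    me <- runif(6, -800, 800)
    ba <- runif(6, -800, 800)
    pm <- match_to_baseline(me, ba)
    or <- match_bruteforce(me, ba)
    expect_equal(sum(abs(pm$deviation_hu)), or$cost, tolerance = 1e-9)
  }

  # length mismatch warns and matches partially
  expect_warning(pp <- match_to_baseline(base[1:5], base), "unmatched plugs")
  expect_equal(nrow(pp), 5L)
})

test_that("contrast grading splits tolerances at water-like HU", {
  base <- stats::setNames(plug_materials()$hu, plug_materials()$material)
  qa3 <- stats::setNames(c(-703.38, -538.26, -41.84, 61.51, 227.09, 409.13, 614.14),
                         1:7)
  graded <- contrast_test(match_to_baseline(qa3, base), qa_config())
  tab <- graded$table

  water <- tab[tab$baseline_name == "Water", ]
  expect_equal(water$deviation_hu, -40.72, tolerance = 1e-9)
  expect_equal(water$tolerance_hu, 30)
  expect_false(water$passed)

  ln300 <- tab[tab$baseline_name == "LN-300", ]
  expect_equal(ln300$deviation_hu, -17.68, tolerance = 1e-9)
  expect_equal(ln300$tolerance_hu, 50)
  expect_true(ln300$passed)

  # zero deviation passes any positive tolerance
  g0 <- contrast_test(match_to_baseline(base, base), qa_config())
  expect_true(g0$all_passed)

  # per-plug overrides replace the default tolerance
  cfg <- qa_config(contrast_tolerance_overrides = c("Water" = 45))
  g2 <- contrast_test(match_to_baseline(qa3, base), cfg)
  expect_true(g2$table$passed[g2$table$baseline_name == "Water"])
})
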