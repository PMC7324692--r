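# DICOM series reader/writer

make_volume <- function(hu_fill = 0, ns = 6, n = 12, seed = NULL,
                        slope = 1, intercept = -1024) {
  hu <- array(hu_fill, dim = c(ns, n, n))
  if (!is.null(seed)) {
    set.seed(seed)
    hu[] <- round(runif(length(hu), -1024, 3000))
  }
  new_volume(hu, c(0.762, 0.762), 1, rescale_slope = slope,
             rescale_intercept = intercept)
}

test_that("write/read round-trip is exact on HU values and metadata", {
  v <- make_volume(seed = 42, ns = 8, n = 20)
  d <- withr::local_tempdir()
  files <- write_series(v, d)
  expect_length(files, 8)
  v2 <- read_series(d)
  expect_identical(dim(v2$hu), dim(v$hu))
  expect_equal(max(abs(v2$hu - v$hu)), 0)
  expect_equal(v2$meta$pixel_spacing_mm, v$meta$pixel_spacing_mm)
  expect_equal(v2$meta$slice_thickness_mm, v$meta$slice_thickness_mm)
  expect_equal(v2$meta$n_slices, v$meta$n_slices)
})

test_that("reading is invariant under file-name permutations", {
  v <- make_volume(seed = 7, ns = 10, n = 10)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_series(v, d1)
  write_series(v, d2)
  set.seed(1)
  old <- list.files(d2, full.names = TRUE)
  new <- file.path(d2, sprintf("zz_%s.dcm", sample(letters, length(old))))
  file.rename(old, new)
  a <- read_series(d1)
  b <- read_series(d2)
  expect_identical(a$hu, b$hu)
})

test_that("stored values are calibrated to HU through slope and intercept", {
  # single slice, stored value 0 everywhere: slope 1, intercept -1024 -> air
  v <- make_volume(hu_fill = -1024, ns = 1)
  d <- withr::local_tempdir()
  write_series(v, d)
  v2 <- read_series(d)
  expect_true(all(v2$hu == -1024))

  # non-trivial calibration round-trips exactly
  hu <- array(2 * (0:35) - 500, dim = c(1, 6, 6))
  vc <- new_volume(hu, c(1, 1), 1, rescale_slope = 2, rescale_intercept = -500)
  dc <- withr::local_tempdir()
  write_series(vc, dc)
  vc2 <- read_series(dc)
  expect_equal(max(abs(vc2$hu - vc$hu)), 0)
  expect_equal(vc2$meta$rescale_slope, 2)
})

test_that("series consistency errors are raised", {
  d <- withr::local_tempdir()
  expect_error(read_series(d), "no DICOM")

  v <- make_volume(ns = 3)
  write_series(v, d)
  # duplicate InstanceNumber: a copied slice file
  file.copy(file.path(d, "slice_0002.dcm"), file.path(d, "zz_copy.dcm"))
  expect_error(read_series(d), "duplicate slice")
  unlink(file.path(d, "zz_copy.dcm"))

  # a slice from another series
  v2 <- make_volume(ns = 1, seed = 3)
  d2 <- withr::local_tempdir()
  write_series(v2, d2)
  file.copy(file.path(d2, "slice_0001.dcm"), file.path(d, "zz_other.dcm"))
  expect_error(read_series(d), "multiple series")
  unlink(file.path(d, "zz_other.dcm"))

  # inconsistent geometry within one series UID
  v3 <- new_volume(array(0, c(1, 12, 12)), c(0.5, 0.5), 2,
                   series_uid = read_series(d)$meta$series_uid)
  d3 <- withr::local_tempdir()
  write_series(v3, d3)
  file.copy(file.path(d3, "slice_0001.dcm"), file.path(d, "zz_geom.dcm"))
  expect_error(read_series(d), "inconsistent geometry")
})

test_that("out-of-range stored values never wrap around silently", {
  hu <- array(4000, dim = c(1, 4, 4))
  v <- new_volume(hu, c(1, 1), 1, rescale_slope = 0.05, rescale_intercept = 0)
  d <- withr::local_tempdir()
  expect_error(write_series(v, d), "stored pixel value")
  files <- write_series(v, d, clamp = TRUE)
  v2 <- read_series(d)
  expect_true(all(v2$hu <= 4000))
})

test_that("missing rescale tags default to slope 1 intercept 0 with a warning", {
  d <- withr::local_tempdir()
  # hand-build a minimal file without rescale tags
  el_str <- mvctqa:::el_str
  el_us <- mvctqa:::el_us
  el_ds <- mvctqa:::el_ds
  dicom_element <- mvctqa:::dicom_element
  raw_u32 <- mvctqa:::raw_u32
  stored <- matrix(100L, 4, 4)
  px_raw <- writeBin(as.integer(t(stored)), raw(), size = 2L, endian = "little")
  dataset <- c(
    el_str(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    el_ds(0x0018, 0x0050, 1),
    el_str(0x0020, 0x000E, "UI", "1.2.3.4"),
    el_str(0x0020, 0x0013, "IS", "1"),
    el_us(0x0028, 0x0010, 4), el_us(0x0028, 0x0011, 4),
    el_ds(0x0028, 0x0030, c(1, 1)),
    el_us(0x0028, 0x0100, 16), el_us(0x0028, 0x0103, 0),
    dicom_element(0x7FE0, 0x0010, "OW", px_raw)
  )
  meta_el <- c(
    el_str(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    el_str(0x0002, 0x0003, "UI", "1.2.3.4.1"),
    el_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  )
  con <- file(file.path(d, "a.dcm"), "wb")
  writeBin(c(raw(128), charToRaw("DICM"),
             dicom_element(0x0002, 0x0000, "UL", raw_u32(length(meta_el))),
             meta_el, dataset), con)
  close(con)
  expect_warning(v <- read_series(d), "Rescale")
  expect_true(all(v$hu == 100))
})

test_that("pydicom independently parses files written by the package", {
  v <- make_volume(seed = 9, ns = 2, n = 8)
  d <- withr::local_tempdir()
  files <- write_series(v, d)
  script <- file.path(d, "check.py")
  out_csv <- file.path(d, "out.csv")
  writeLines(sprintf(paste0(
    "import pydicom\n",
    "ds = pydicom.dcmread(r'%s')\n",
    "arr = ds.pixel_array.astype(float) * float(ds.RescaleSlope) + float(ds.RescaleIntercept)\n",
    "import numpy as np\n",
    "np.savetxt(r'%s', arr, delimiter=',')\n",
    "print(int(ds.InstanceNumber), float(ds.SliceThickness))\n"),
    files[2], out_csv), script)
  res <- suppressWarnings(system2("python", shQuote(script), stdout = TRUE, stderr = TRUE))
  expect_true(file.exists(out_csv))
  expect_match(res[length(res)], "^2 1")
  arr <- as.matrix(utils::read.csv(out_csv, header = FALSE))
  expect_equal(max(abs(arr - v$hu[2, , ])), 0)
})
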