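# orchestration, baselines, reports

qa_fixture <- function() {
  fixture("qa_run", {
    g <- std_phantom()
    r0 <- run_qa(g$volume, baseline = NULL)
    bl_path <- file.path(tempdir(), "mvctqa-test-baseline.json")
    save_baseline(r0, bl_path)
    r1 <- run_qa(g$volume, baseline = bl_path, resolution_grade = "pass")
    list(g = g, r0 = r0, bl_path = bl_path, r1 = r1)
  })
}

test_that("self-comparison yields zero deviations and overall pass", {
  fx <- qa_fixture()
  expect_identical(fx$r0$overall_status, "incomplete")   # ungraded, no baseline
  expect_identical(fx$r0$geometric$status, "baseline established")

  r1 <- fx$r1
  expect_identical(r1$overall_status, "pass")
  expect_true(all(r1$geometric$table$deviation_mm == 0))
  expect_true(all(r1$contrast$table$deviation_hu == 0))
})

test_that("an injected scale error fails the SRS geometric test and the QA", {
  fx <- qa_fixture()
  v2 <- inject_distortion(fx$g$volume, c(1.02, 1.02))
  r2 <- run_qa(v2, baseline = fx$bl_path, config = qa_config(mode = "srs"),
               resolution_grade = "pass")
  expect_false(r2$geometric$passed)
  expect_identical(r2$overall_status, "fail")
})

test_that("baselines round-trip exactly and reject bad files", {
  fx <- qa_fixture()
  bl <- load_baseline(fx$bl_path)
  expect_s3_class(bl, "baseline_record")
  expect_equal(unname(bl$geometric_mm),
               fx$r0$geometric$table$measured_mm, tolerance = 0)
  expect_identical(bl$contrast$label, plug_materials()$material)
  expect_equal(bl$contrast$hu, fx$r0$contrast_measured$mean_hu, tolerance = 0)

  # corrupt JSON names the file
  bad <- file.path(tempdir(), "truncated.json")
  txt <- readLines(fx$bl_path)
  writeLines(substr(paste(txt, collapse = ""), 1, 50), bad)
  expect_error(load_baseline(bad), "truncated.json")

  # version mismatch
  rec <- jsonlite::fromJSON(fx$bl_path)
  rec$format_version <- "99.0"
  v99 <- file.path(tempdir(), "v99.json")
  jsonlite::write_json(rec, v99, auto_unbox = TRUE)
  expect_error(load_baseline(v99), "unsupported baseline version")
})

test_that("overall status aggregates pass/fail/incomplete correctly", {
  fx <- qa_fixture()
  r <- fx$r1
  expect_identical(r$overall_status, "pass")

  # ungraded resolution -> incomplete
  r_un <- run_qa(fx$g$volume, baseline = fx$bl_path)
  expect_identical(r_un$resolution$visual_grade, "ungraded")
  expect_identical(r_un$overall_status, "incomplete")

  # failing resolution alone fails the QA
  r_f <- record_visual_grade(r_un, "fail")
  expect_identical(r_f$overall_status, "fail")

  # grading after the fact recomputes the stored status
  r_p <- record_visual_grade(r_un, "pass")
  expect_identical(r_p$overall_status, "pass")
})

test_that("report rendering writes a one-page PDF, PNG and faithful sidecar", {
  fx <- qa_fixture()
  out_dir <- withr::local_tempdir()
  files <- render_report(fx$r1, out_dir, volume = fx$g$volume)
  expect_true(file.exists(files$pdf))
  expect_true(file.exists(files$json))
  expect_true(file.exists(files$png))

  # exactly one page
  lines <- readLines(files$pdf, warn = FALSE, skipNul = TRUE)
  n_pages <- sum(grepl("/Type /Page(?!s)", lines, perl = TRUE, useBytes = TRUE))
  expect_identical(n_pages, 1L)

  # sidecar numerically identical to the in-memory report
  side <- read_report_json(files$json)
  expect_equal(side$geometric$table$measured_mm,
               fx$r1$geometric$table$measured_mm, tolerance = 0)
  expect_equal(side$contrast$table$deviation_hu,
               fx$r1$contrast$table$deviation_hu, tolerance = 0)
  expect_equal(side$uniformity$max_abs_diff_hu,
               fx$r1$uniformity$max_abs_diff_hu, tolerance = 0)
  expect_identical(side$overall_status, "pass")
})

test_that("identical runs produce byte-identical JSON sidecars", {
  fx <- qa_fixture()
  p1 <- file.path(tempdir(), "sidecar-a.json")
  p2 <- file.path(tempdir(), "sidecar-b.json")
  write_report_json(fx$r1, p1)
  r_again <- run_qa(fx$g$volume, baseline = fx$bl_path, resolution_grade = "pass")
  write_report_json(r_again, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("tidy and glance summarize a report", {
  fx <- qa_fixture()
  td <- tidy(fx$r1)
  expect_true(all(c("test", "item", "value", "tolerance", "passed") %in% names(td)))
  expect_setequal(unique(td$test),
                  c("geometric", "uniformity", "noise", "contrast", "resolution"))
  expect_identical(sum(td$passed %in% FALSE), 0L)

  gl <- glance(fx$r1)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$overall_status, "pass")
  expect_equal(gl$max_geometric_deviation_mm, 0)
})

test_that("the command-line interface drives the full pipeline", {
  cli <- system.file("exec", "mvctqa", package = "mvctqa")
  expect_true(file.exists(cli))
  dicom_dir <- file.path(withr::local_tempdir(), "series")
  rsc <- file.path(R.home("bin"), "Rscript")
  run <- function(...) {
    suppressWarnings(system2(rsc, c(shQuote(cli), ...), stdout = TRUE, stderr = TRUE))
  }
  run("simulate", "--out", shQuote(dicom_dir), "--seed", "2", "--preset", "coarse")
  expect_gt(length(list.files(dicom_dir)), 100)
  bl <- file.path(dirname(dicom_dir), "bl.json")
  run("baseline", shQuote(dicom_dir), "--out", shQuote(bl))
  expect_true(file.exists(bl))
  out_dir <- file.path(dirname(dicom_dir), "out")
  log <- run("run", shQuote(dicom_dir), "--baseline", shQuote(bl),
             "--grade-resolution", "pass", "--out", shQuote(out_dir))
  expect_true(file.exists(file.path(out_dir, "qa_report.pdf")))
  side <- read_report_json(file.path(out_dir, "qa_report.json"))
  expect_identical(side$overall_status, "pass")
})
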