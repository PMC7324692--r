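#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a QA report into one row per graded item
#'
#' @param x a `qa_report`.
#' @param ... unused.
#' @return A tibble with columns `test`, `item`, `value`, `baseline`,
#'   `deviation`, `tolerance`, `unit`, `passed` (`NA` for informational or
#'   ungraded items).
#' @export
tidy.qa_report <- function(x, ...) {
  rows <- list()
  if (!is.null(x$geometric)) {
    g <- x$geometric
    rows$geo <- tibble::tibble(
      test = "geometric", item = g$table$label,
      value = g$table$measured_mm, baseline = g$table$baseline_mm,
      deviation = g$table$deviation_mm,
      tolerance = g$tolerance_mm, unit = "mm",
      passed = if (isTRUE(is.na(g$passed))) NA else
        abs(g$table$deviation_mm) <= g$tolerance_mm + 1e-9
    )
  }
  if (!is.null(x$uniformity)) {
    u <- x$uniformity
    rows$uni <- tibble::tibble(
      test = "uniformity", item = "max_center_periphery_diff",
      value = u$max_abs_diff_hu, baseline = NA_real_, deviation = NA_real_,
      tolerance = u$tolerance_hu, unit = "HU", passed = u$passed
    )
  }
  if (!is.null(x$noise)) {
    n <- x$noise
    rows$noise <- tibble::tibble(
      test = "noise", item = c("sigma_small", "sigma_big"),
      value = c(n$sigma_small_hu, n$sigma_big_hu),
      baseline = NA_real_, deviation = NA_real_,
      tolerance = NA_real_, unit = "HU", passed = NA
    )
  }
  if (!is.null(x$contrast)) {
    ct <- x$contrast$table
    rows$contrast <- tibble::tibble(
      test = "contrast", item = ct$baseline_name,
      value = ct$measured_hu, baseline = ct$baseline_hu,
      deviation = ct$deviation_hu, tolerance = ct$tolerance_hu,
      unit = "HU", passed = ct$passed
    )
  } else if (!is.null(x$contrast_measured)) {
    cm <- x$contrast_measured
    rows$contrast <- tibble::tibble(
      test = "contrast", item = paste0("hole-", cm$hole),
      value = cm$mean_hu, baseline = NA_real_, deviation = NA_real_,
      tolerance = NA_real_, unit = "HU", passed = NA
    )
  }
  if (!is.null(x$resolution)) {
    r <- x$resolution
    rows$res <- tibble::tibble(
      test = "resolution", item = "visual_grade",
      value = NA_real_, baseline = NA_real_, deviation = NA_real_,
      tolerance = r$criterion_mm, unit = "mm",
      passed = switch(r$visual_grade, pass = TRUE, fail = FALSE, NA)
    )
  }
  dplyr::bind_rows(rows)
}

#' One-row summary of a QA report
#'
#' @param x a `qa_report`.
#' @param ... unused.
#' @return A one-row tibble.
#' @export
glance.qa_report <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    overall_status = x$overall_status,
    mode = if (!is.null(x$geometric)) x$geometric$mode else NA_character_,
    n_items = nrow(td),
    n_failed = sum(td$passed %in% FALSE),
    max_geometric_deviation_mm = if (!is.null(x$geometric))
      max(abs(x$geometric$table$deviation_mm)) else NA_real_,
    uniformity_hu = if (!is.null(x$uniformity)) x$uniformity$max_abs_diff_hu else NA_real_,
    noise_sigma_small_hu = if (!is.null(x$noise)) x$noise$sigma_small_hu else NA_real_,
    noise_sigma_big_hu = if (!is.null(x$noise)) x$noise$sigma_big_hu else NA_real_,
    max_contrast_deviation_hu = if (!is.null(x$contrast))
      max(abs(x$contrast$table$deviation_hu)) else NA_real_,
    resolution_grade = if (!is.null(x$resolution)) x$resolution$visual_grade else "ungraded"
  )
}
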