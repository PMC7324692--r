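Package: mvctqa
Title: Automated Image Quality Assurance for Helical Tomotherapy MVCT
    Phantom Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated monthly image-quality assurance for mega-voltage CT
    (MVCT) scans of the cylindrical water-equivalent "cheese" phantom used on
    helical tomotherapy platforms. Reads a DICOM series into a calibrated
    Hounsfield-unit volume, detects the embedded fiducial markers, and grades
    geometric distortion, uniformity, noise, contrast-plug constancy and
    spatial-resolution plug localization against configurable TG-148-style
    tolerances and a persisted baseline, emitting a one-page PDF report with a
    machine-readable JSON sidecar. Includes a synthetic phantom simulator with
    exact ground truth, and a writer that emits standard DICOM series, so the
    whole pipeline can be exercised without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grid,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    patchwork,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
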