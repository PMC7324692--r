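#' DICOM series input/output
#'
#' Minimal, dependency-free reader and writer for uncompressed single-frame
#' CT DICOM files (explicit and implicit VR little endian). The reader
#' assembles one series folder into a calibrated [new_volume()] HU volume,
#' sorting slices by `InstanceNumber`; the writer emits one valid DICOM file
#' per slice so that synthetic phantoms round-trip through the same path as
#' scanner data.
#'
#' @name dicom_io
NULL

DICOM_TS_IMPLICIT <- "1.2.840.10008.1.2"
DICOM_TS_EXPLICIT <- "1.2.840.10008.1.2.1"
DICOM_SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"
DICOM_IMPL_UID <- "1.2.826.0.1.3680043.10.1462.1"

# ---- low-level byte helpers -------------------------------------------------

raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")

raw_u32 <- function(x) {
  x <- as.numeric(x)
  lo <- x %% 65536
  hi <- (x - lo) / 65536
  c(raw_u16(lo), raw_u16(hi))
}

read_u16 <- function(r, pos) {
  as.integer(r[pos]) + 256L * as.integer(r[pos + 1L])
}

read_u32 <- function(r, pos) {
  # double-valued to stay safe for lengths >= 2^31
  as.numeric(read_u16(r, pos)) + 65536 * as.numeric(read_u16(r, pos + 2L))
}

# pad a string value to even length; UI pads with NUL, text VRs with space
str_value_raw <- function(s, pad = as.raw(0x20)) {
  v <- charToRaw(s)
  if (length(v) %% 2L == 1L) v <- c(v, pad)
  v
}

# raw bytes -> string, dropping NUL padding and trailing spaces
raw_to_str <- function(v) {
  v <- v[v != as.raw(0)]
  sub(" +$", "", rawToChar(v))
}

ds_format <- function(x) {
  # DS values are limited to 16 bytes each
  vapply(x, function(v) {
    s <- formatC(v, digits = 10, format = "g", flag = "")
    gsub(" ", "", s)
  }, character(1))
}

# ---- element encoders (explicit VR little endian) ---------------------------

dicom_element <- function(group, element, vr, value_raw) {
  tag <- c(raw_u16(group), raw_u16(element))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(tag, charToRaw(vr), as.raw(c(0, 0)), raw_u32(length(value_raw)), value_raw)
  } else {
    c(tag, charToRaw(vr), raw_u16(length(value_raw)), value_raw)
  }
}

el_str <- function(group, element, vr, s) {
  pad <- if (vr == "UI") as.raw(0) else as.raw(0x20)
  dicom_element(group, element, vr, str_value_raw(s, pad))
}

el_us <- function(group, element, x) dicom_element(group, element, "US", raw_u16(x))

el_ds <- function(group, element, x) {
  el_str(group, element, "DS", paste(ds_format(x), collapse = "\\"))
}

# ---- writer -----------------------------------------------------------------

#' Write a volume as a DICOM series
#'
#' Emits one explicit-VR little-endian CT file per slice with
#' `InstanceNumber` 1..n and the geometry/rescale tags needed to reconstruct
#' the volume. Stored pixel values are `(hu - intercept) / slope`, rounded;
#' with the default calibration (slope 1, intercept -1024) integer HU arrays
#' round-trip exactly.
#'
#' @param volume an [new_volume()] object. HU values should be integral for
#'   an exact round-trip (the synthetic generator quantizes to integer HU,
#'   as any CT reconstruction does).
#' @param folder_path output directory, created if needed.
#' @param clamp if `TRUE`, stored values outside the representable 16-bit
#'   range are clamped; if `FALSE` (default) they raise an error. There is
#'   never silent wraparound.
#' @return Invisibly, the character vector of files written (in slice order).
#' @export
write_series <- function(volume, folder_path, clamp = FALSE) {
  stopifnot(inherits(volume, "mvct_volume"))
  if (!dir.exists(folder_path)) {
    ok <- dir.create(folder_path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) qa_abort(sprintf("cannot create folder '%s'", folder_path), "io_error")
  }
  meta <- volume$meta
  slope <- meta$rescale_slope
  intercept <- meta$rescale_intercept
  series_uid <- meta$series_uid
  if (!nzchar(series_uid)) {
    series_uid <- sprintf("1.2.826.0.1.3680043.10.1462.%d.%d.%.0f",
                          dim(volume$hu)[2L], meta$n_slices,
                          abs(sum(volume$hu)) %% 1e7)
  }
  study_uid <- paste0(series_uid, ".0")

  ns <- meta$n_slices
  nr <- dim(volume$hu)[2L]
  nc <- dim(volume$hu)[3L]
  files <- character(ns)
  for (i in seq_len(ns)) {
    stored <- round((volume$hu[i, , ] - intercept) / slope)
    if (any(stored < 0 | stored > 65535)) {
      if (clamp) {
        stored <- pmin(pmax(stored, 0), 65535)
      } else {
        qa_abort("stored pixel value out of 16-bit range (set clamp = TRUE to clamp)",
                 "stored_range")
      }
    }
    # row-major pixel order; values > 32767 are written via two's complement,
    # never by modular wraparound of the HU value itself
    v <- as.integer(t(stored))
    v <- ifelse(v > 32767L, v - 65536L, v)
    pixel_raw <- writeBin(v, raw(), size = 2L, endian = "little")

    dataset <- c(
      el_str(0x0008, 0x0016, "UI", DICOM_SOP_CT),
      el_str(0x0008, 0x0018, "UI", sprintf("%s.%d", series_uid, i)),
      el_str(0x0008, 0x0060, "CS", "CT"),
      el_ds(0x0018, 0x0050, meta$slice_thickness_mm),
      el_str(0x0020, 0x000D, "UI", study_uid),
      el_str(0x0020, 0x000E, "UI", series_uid),
      el_str(0x0020, 0x0013, "IS", as.character(i)),
      el_ds(0x0020, 0x0032, c(0, 0, (i - 1) * meta$slice_thickness_mm)),
      el_us(0x0028, 0x0002, 1),
      el_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      el_us(0x0028, 0x0010, nr),
      el_us(0x0028, 0x0011, nc),
      el_ds(0x0028, 0x0030, meta$pixel_spacing_mm),
      el_us(0x0028, 0x0100, 16),
      el_us(0x0028, 0x0101, 16),
      el_us(0x0028, 0x0102, 15),
      el_us(0x0028, 0x0103, 0),
      el_ds(0x0028, 0x1052, intercept),
      el_ds(0x0028, 0x1053, slope),
      dicom_element(0x7FE0, 0x0010, "OW", pixel_raw)
    )

    meta_elements <- c(
      dicom_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      el_str(0x0002, 0x0002, "UI", DICOM_SOP_CT),
      el_str(0x0002, 0x0003, "UI", sprintf("%s.%d", series_uid, i)),
      el_str(0x0002, 0x0010, "UI", DICOM_TS_EXPLICIT),
      el_str(0x0002, 0x0012, "UI", DICOM_IMPL_UID)
    )
    file_meta <- c(
      dicom_element(0x0002, 0x0000, "UL", raw_u32(length(meta_elements))),
      meta_elements
    )

    path <- file.path(folder_path, sprintf("slice_%04d.dcm", i))
    con <- file(path, "wb")
    writeBin(c(raw(128L), charToRaw("DICM"), file_meta, dataset), con)
    close(con)
    files[i] <- path
  }
  invisible(files)
}

# ---- parser -----------------------------------------------------------------

long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# parse one DICOM file into a named tag list plus stored pixel matrix
parse_dicom_file <- function(path) {
  r <- readBin(path, raw(), file.size(path))
  if (length(r) < 140L || rawToChar(r[129:132]) != "DICM") {
    qa_abort(sprintf("'%s' is not a DICOM file", basename(path)), "not_dicom")
  }
  pos <- 133L
  ts <- DICOM_TS_EXPLICIT
  tags <- list()

  read_element <- function(pos, explicit) {
    group <- read_u16(r, pos)
    element <- read_u16(r, pos + 2L)
    if (explicit) {
      vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- read_u32(r, pos + 8L)
        vstart <- pos + 12L
      } else {
        len <- read_u16(r, pos + 6L)
        vstart <- pos + 8L
      }
    } else {
      vr <- NA_character_
      len <- read_u32(r, pos + 4L)
      vstart <- pos + 8L
    }
    if (len == 4294967295) {
      qa_abort(sprintf("undefined-length element (%04X,%04X) unsupported", group, element),
               "unsupported_dicom")
    }
    list(group = group, element = element, vr = vr,
         value = if (len > 0) r[vstart:(vstart + len - 1L)] else raw(0),
         next_pos = vstart + as.integer(len))
  }

  # file meta group is always explicit VR
  while (pos + 7L <= length(r) && read_u16(r, pos) == 0x0002) {
    el <- read_element(pos, explicit = TRUE)
    if (el$element == 0x0010) ts <- raw_to_str(el$value)
    pos <- el$next_pos
  }
  if (!ts %in% c(DICOM_TS_EXPLICIT, DICOM_TS_IMPLICIT)) {
    qa_abort(sprintf("unsupported transfer syntax '%s' in '%s'", ts, basename(path)),
             "unsupported_dicom")
  }
  explicit <- identical(ts, DICOM_TS_EXPLICIT)

  while (pos + 7L <= length(r)) {
    el <- read_element(pos, explicit)
    key <- sprintf("%04X,%04X", el$group, el$element)
    tags[[key]] <- el
    pos <- el$next_pos
  }

  get_str <- function(key) {
    el <- tags[[key]]
    if (is.null(el) || length(el$value) == 0L) return(NA_character_)
    raw_to_str(el$value)
  }
  get_ds <- function(key) {
    s <- get_str(key)
    if (is.na(s)) return(NA_real_)
    as.numeric(strsplit(s, "\\\\")[[1]])
  }
  get_us <- function(key) {
    el <- tags[[key]]
    if (is.null(el)) return(NA_integer_)
    read_u16(el$value, 1L)
  }

  rows <- get_us("0028,0010")
  cols <- get_us("0028,0011")
  bits <- get_us("0028,0100")
  pixrep <- get_us("0028,0103")
  if (is.na(rows) || is.na(cols)) {
    qa_abort(sprintf("'%s' has no image dimensions", basename(path)), "not_dicom")
  }
  if (!is.na(bits) && !bits %in% c(8L, 16L)) {
    qa_abort(sprintf("unsupported BitsAllocated %d in '%s'", bits, basename(path)),
             "unsupported_dicom")
  }
  px <- tags[["7FE0,0010"]]
  if (is.null(px)) {
    qa_abort(sprintf("'%s' has no pixel data", basename(path)), "not_dicom")
  }
  size <- if (identical(bits, 8L)) 1L else 2L
  stored <- readBin(px$value, "integer", n = rows * cols, size = size,
                    signed = identical(pixrep, 1L), endian = "little")
  if (identical(pixrep, 0L) && size == 2L) {
    stored <- ifelse(stored < 0L, stored + 65536L, stored)
  }

  list(
    instance_number = suppressWarnings(as.integer(get_str("0020,0013"))),
    series_uid = get_str("0020,000E"),
    pixel_spacing = get_ds("0028,0030"),
    slice_thickness = get_ds("0018,0050")[1],
    rescale_slope = get_ds("0028,1053")[1],
    rescale_intercept = get_ds("0028,1052")[1],
    position = get_ds("0020,0032"),
    rows = rows, cols = cols,
    stored = matrix(stored, nrow = rows, byrow = TRUE)
  )
}

#' Read a DICOM series folder into an HU volume
#'
#' All readable DICOM files in `folder_path` are parsed, checked for
#' consistency (one series, one geometry, unique slice numbers), sorted by
#' ascending `InstanceNumber` and stacked. Stored pixel values are converted
#' to HU via `RescaleSlope`/`RescaleIntercept`; files without rescale tags
#' are treated as slope 1, intercept 0, with a warning. If `InstanceNumber`
#' is absent everywhere, slices are ordered by the longitudinal component of
#' `ImagePositionPatient`, with a warning. The result is independent of file
#' names and directory listing order.
#'
#' @param folder_path directory containing one DICOM series.
#' @return An [new_volume()] object.
#' @export
read_series <- function(folder_path) {
  if (!dir.exists(folder_path)) {
    qa_abort(sprintf("no DICOM found: '%s' is not a directory", folder_path), "no_dicom")
  }
  files <- list.files(folder_path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  parsed <- list()
  for (f in files) {
    p <- tryCatch(parse_dicom_file(f), mvctqa_error = function(e) {
      if (inherits(e, "unsupported_dicom")) rlang::abort(conditionMessage(e), class = "unsupported_dicom")
      NULL
    })
    if (!is.null(p)) parsed[[length(parsed) + 1L]] <- p
  }
  if (length(parsed) == 0L) {
    qa_abort(sprintf("no DICOM found in '%s'", folder_path), "no_dicom")
  }

  uids <- unique(stats::na.omit(vapply(parsed, `[[`, "", "series_uid")))
  if (length(uids) > 1L) {
    qa_abort(sprintf("multiple series in folder (%s)", paste(uids, collapse = ", ")),
             "multiple_series")
  }

  spacing <- t(vapply(parsed, function(p) p$pixel_spacing[1:2], numeric(2)))
  thick <- vapply(parsed, `[[`, numeric(1), "slice_thickness")
  dims <- t(vapply(parsed, function(p) c(p$rows, p$cols), integer(2)))
  same <- function(m) all(abs(sweep(m, 2, m[1, ])) < 1e-9)
  if (anyNA(spacing) || anyNA(thick) ||
      !same(spacing) || max(thick) - min(thick) > 1e-9 || !same(dims)) {
    qa_abort("inconsistent geometry: PixelSpacing/SliceThickness/matrix size differ across files",
             "inconsistent_geometry")
  }

  inst <- vapply(parsed, `[[`, integer(1), "instance_number")
  if (all(is.na(inst))) {
    qa_warn("InstanceNumber absent; ordering slices by ImagePositionPatient",
            "no_instance_number")
    posn <- vapply(parsed, function(p) p$position[3], numeric(1))
    if (anyNA(posn)) qa_abort("cannot order slices: no InstanceNumber or position", "no_dicom")
    ord <- order(posn)
  } else {
    if (anyNA(inst)) qa_abort("some files lack InstanceNumber", "duplicate_slice")
    if (anyDuplicated(inst)) {
      qa_abort(sprintf("duplicate slice: InstanceNumber %s repeated",
                       paste(unique(inst[duplicated(inst)]), collapse = ", ")),
               "duplicate_slice")
    }
    ord <- order(inst)
    si <- sort(inst)
    if (any(diff(si) != 1L)) {
      qa_warn("InstanceNumber sequence has gaps; proceeding with sorted order",
              "instance_gaps")
    }
  }
  parsed <- parsed[ord]

  no_rescale <- vapply(parsed, function(p) is.na(p$rescale_slope) && is.na(p$rescale_intercept),
                       logical(1))
  if (any(no_rescale)) {
    qa_warn("RescaleSlope/Intercept missing; assuming slope 1, intercept 0",
            "no_rescale")
  }

  ns <- length(parsed)
  hu <- array(0, dim = c(ns, parsed[[1]]$rows, parsed[[1]]$cols))
  for (i in seq_len(ns)) {
    p <- parsed[[i]]
    slope <- if (is.na(p$rescale_slope)) 1 else p$rescale_slope
    intercept <- if (is.na(p$rescale_intercept)) 0 else p$rescale_intercept
    hu[i, , ] <- slope * p$stored + intercept
  }
  if (min(hu) < -1024 || max(hu) > 4000) {
    qa_warn("HU values outside [-1024, 4000] clamped", "hu_clamped")
    hu <- pmin(pmax(hu, -1024), 4000)
  }

  new_volume(
    hu,
    pixel_spacing_mm = parsed[[1]]$pixel_spacing[1:2],
    slice_thickness_mm = parsed[[1]]$slice_thickness,
    rescale_slope = if (is.na(parsed[[1]]$rescale_slope)) 1 else parsed[[1]]$rescale_slope,
    rescale_intercept = if (is.na(parsed[[1]]$rescale_intercept)) 0 else parsed[[1]]$rescale_intercept,
    series_uid = if (length(uids)) uids else ""
  )
}
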