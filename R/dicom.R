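## Minimal single-frame CT DICOM reader/writer.
##
## Scope: uncompressed Explicit VR Little Endian is written; Explicit and
## Implicit VR Little Endian are read. This covers the output of this
## package and typical scanner exports of single-frame CT images. No
## sequences with pixel data, no multi-frame, no compressed transfer
## syntaxes. Implemented here because no DICOM library is available in the
## supported environment.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
SOP_CT_IMAGE <- "1.2.840.10008.5.1.4.1.1.2"
UID_ROOT <- "1.2.826.0.1.3680043.10.424" # ad-hoc org root for generated UIDs

# ---- byte helpers ----------------------------------------------------------

raw_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
raw_uint32 <- function(x) {
  # writeBin has no unsigned 32-bit; lengths here stay far below 2^31
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

pad_even <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

# VRs with a 2-byte reserved field and 4-byte length in explicit VR
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_element <- function(group, element, vr, value_bytes) {
  if (vr %in% c("UI")) value_bytes <- pad_even(value_bytes, as.raw(0x00))
  else if (vr %in% c("OB", "OW")) value_bytes <- pad_even(value_bytes, as.raw(0x00))
  else value_bytes <- pad_even(value_bytes)
  hdr <- c(raw_uint16(group), raw_uint16(element), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    hdr <- c(hdr, as.raw(c(0, 0)), raw_uint32(length(value_bytes)))
  } else {
    hdr <- c(hdr, raw_uint16(length(value_bytes)))
  }
  c(hdr, value_bytes)
}

dcm_str <- function(group, element, vr, s) {
  dcm_element(group, element, vr, charToRaw(as.character(s)))
}

dcm_us <- function(group, element, x) {
  dcm_element(group, element, "US", raw_uint16(x))
}

# decimal string with enough digits to round-trip positions exactly
fmt_ds <- function(x) {
  s <- formatC(x, format = "g", digits = 15)
  if (nchar(s) > 16L) s <- formatC(x, format = "g", digits = 10)
  s
}

# small deterministic content hash for UID generation (31-bit polynomial)
content_hash <- function(values) {
  bytes <- as.integer(writeBin(as.numeric(values), raw(), size = 8))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  format(h, scientific = FALSE)
}

# ---- writer ----------------------------------------------------------------

#' Write an image series as a DICOM directory
#'
#' Writes one single-frame CT DICOM file per slice (Explicit VR Little
#' Endian), storing pixel values as signed 16-bit integers with the given
#' rescale slope and intercept so that `slope * stored + intercept`
#' reproduces HU to within one stored-value quantum. Slice position is
#' written both as the z component of Image Position (Patient) and as the
#' Slice Location tag.
#'
#' @param series a [image_series()] object.
#' @param path output directory; created if missing.
#' @param slope,intercept rescale mapping used for integer storage. The
#'   defaults (slope 1, intercept -1024) follow common CT convention.
#' @param series_uid optional Series Instance UID; by default a
#'   deterministic UID is derived from the series content, so identical
#'   series produce identical files.
#' @return Invisibly, the character vector of files written.
#' @export
write_series <- function(series, path, slope = 1, intercept = -1024,
                         series_uid = NULL) {
  if (!inherits(series, "ctssp_series"))
    stop_input("'series' must be an image_series object")
  if (any(diff(series$z) <= 0))
    stop_input("refusing to write a series with duplicate or unordered slice positions")
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_input(sprintf("cannot create output directory '%s'", path))
  }
  if (file.access(path, mode = 2L) != 0L)
    stop_input(sprintf("output directory '%s' is not writable", path))
  if (is.null(series_uid))
    series_uid <- paste0(UID_ROOT, ".1.",
                         content_hash(c(series$z,
                                        dim(series$slices[[1]]$pixels),
                                        series$slices[[1]]$pixels)))

  n <- length(series$slices)
  files <- character(n)
  for (i in seq_len(n)) {
    sl <- series$slices[[i]]
    stored <- round((sl$pixels - intercept) / slope)
    if (any(stored < -32768 | stored > 32767))
      stop_input("HU values out of range for signed 16-bit storage with the given rescale")
    d <- dim(stored)
    sop_uid <- paste0(series_uid, ".", i)
    # pixel data in DICOM row-major order
    px <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")

    ds <- c(
      dcm_str(0x0008, 0x0016, "UI", SOP_CT_IMAGE),
      dcm_str(0x0008, 0x0018, "UI", sop_uid),
      dcm_str(0x0008, 0x0060, "CS", "CT"),
      dcm_str(0x0020, 0x000E, "UI", series_uid),
      dcm_str(0x0020, 0x0013, "IS", as.character(i)),
      dcm_str(0x0020, 0x0032, "DS",
              paste(fmt_ds(0), fmt_ds(0), fmt_ds(sl$z), sep = "\\")),
      dcm_str(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
      dcm_str(0x0020, 0x1041, "DS", fmt_ds(sl$z)),
      dcm_str(0x0018, 0x0050, "DS", fmt_ds(sl$thickness)),
      dcm_us(0x0028, 0x0002, 1L),
      dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_us(0x0028, 0x0010, d[1L]),
      dcm_us(0x0028, 0x0011, d[2L]),
      dcm_str(0x0028, 0x0030, "DS",
              paste(fmt_ds(sl$pixel_spacing[1L]), fmt_ds(sl$pixel_spacing[2L]),
                    sep = "\\")),
      dcm_us(0x0028, 0x0100, 16L),
      dcm_us(0x0028, 0x0101, 16L),
      dcm_us(0x0028, 0x0102, 15L),
      dcm_us(0x0028, 0x0103, 1L),
      dcm_str(0x0028, 0x1052, "DS", fmt_ds(intercept)),
      dcm_str(0x0028, 0x1053, "DS", fmt_ds(slope)),
      dcm_element(0x7FE0, 0x0010, "OW", px)
    )

    meta_body <- c(
      dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      dcm_str(0x0002, 0x0002, "UI", SOP_CT_IMAGE),
      dcm_str(0x0002, 0x0003, "UI", sop_uid),
      dcm_str(0x0002, 0x0010, "UI", TS_EXPLICIT_LE),
      dcm_str(0x0002, 0x0012, "UI", paste0(UID_ROOT, ".0.1"))
    )
    meta <- c(dcm_element(0x0002, 0x0000, "UL", raw_uint32(length(meta_body))),
              meta_body)

    f <- file.path(path, sprintf("slice_%04d.dcm", i))
    con <- file(f, "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
    close(con)
    files[i] <- f
  }
  invisible(files)
}

# ---- reader ----------------------------------------------------------------

# VR dictionary for implicit-VR parsing of the tags this reader consumes
IMPLICIT_VR <- list(
  "0008,0016" = "UI", "0008,0018" = "UI", "0008,0060" = "CS",
  "0020,000E" = "UI", "0020,0013" = "IS", "0020,0032" = "DS",
  "0020,0037" = "DS", "0020,1041" = "DS", "0018,0050" = "DS",
  "0028,0002" = "US", "0028,0004" = "CS", "0028,0010" = "US",
  "0028,0011" = "US", "0028,0030" = "DS", "0028,0100" = "US",
  "0028,0101" = "US", "0028,0102" = "US", "0028,0103" = "US",
  "0028,1052" = "DS", "0028,1053" = "DS", "7FE0,0010" = "OW"
)

u16 <- function(bytes, at) {
  readBin(bytes[at:(at + 1L)], "integer", size = 2, signed = FALSE,
          endian = "little")
}
u32 <- function(bytes, at) {
  v <- readBin(bytes[at:(at + 3L)], "integer", size = 4, endian = "little")
  if (v < 0) v <- v + 4294967296
  v
}

tag_key <- function(group, element) {
  sprintf("%04X,%04X", group, element)
}

# parse one dataset (explicit or implicit VR LE); returns named list of
# raw values plus their VRs
parse_dataset <- function(bytes, at, explicit) {
  out <- list()
  n <- length(bytes)
  while (at + 7L <= n) {
    group <- u16(bytes, at); element <- u16(bytes, at + 2L)
    at <- at + 4L
    if (explicit) {
      vr <- rawToChar(bytes[at:(at + 1L)])
      if (vr %in% LONG_VRS) {
        len <- u32(bytes, at + 4L); at <- at + 8L
      } else {
        len <- u16(bytes, at + 2L); at <- at + 4L
      }
    } else {
      vr <- IMPLICIT_VR[[tag_key(group, element)]]
      if (is.null(vr)) vr <- "UN"
      len <- u32(bytes, at); at <- at + 4L
    }
    if (len == 4294967295) # undefined length (sequence) — skip unsupported
      stop_input("unsupported DICOM element with undefined length")
    if (at + len - 1L > n)
      stop_input("truncated DICOM element")
    key <- tag_key(group, element)
    if (!is.null(IMPLICIT_VR[[key]])) {
      value <- if (len > 0L) bytes[at:(at + len - 1L)] else raw(0)
      out[[key]] <- list(vr = vr, bytes = value)
    }
    at <- at + len
  }
  out
}

bytes_to_str <- function(bytes) {
  trimws(rawToChar(bytes[bytes != as.raw(0)]))
}

val_str <- function(el) {
  if (is.null(el) || length(el$bytes) == 0L) return(NULL)
  bytes_to_str(el$bytes)
}
val_ds <- function(el) {
  s <- val_str(el)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
val_us <- function(el) {
  if (is.null(el)) return(NULL)
  u16(el$bytes, 1L)
}

read_dicom_file <- function(f) {
  bytes <- readBin(f, raw(), n = file.size(f))
  if (length(bytes) < 140L) stop_input(sprintf("'%s' is too small to be DICOM", f))
  at <- 1L
  ts <- TS_IMPLICIT_LE
  if (length(bytes) >= 132L && rawToChar(bytes[129:132]) == "DICM") {
    at <- 133L
    # file meta group: always explicit VR LE; first element gives its length
    g <- u16(bytes, at)
    if (g != 0x0002L) stop_input(sprintf("'%s': missing file meta group", f))
    meta_len <- u32(bytes, at + 8L) # (0002,0000) UL, 2-byte len at +6, value at +8
    meta_end <- at + 12L + meta_len
    meta <- parse_meta(bytes, at + 12L, meta_end)
    if (!is.null(meta$ts)) ts <- meta$ts
    at <- meta_end
  }
  explicit <- ts == TS_EXPLICIT_LE
  if (!explicit && ts != TS_IMPLICIT_LE)
    stop_input(sprintf("'%s': unsupported transfer syntax %s (compressed or big-endian)", f, ts))
  els <- parse_dataset(bytes, at, explicit)

  rows <- val_us(els[["0028,0010"]]); cols <- val_us(els[["0028,0011"]])
  if (is.null(rows) || is.null(cols))
    stop_input(sprintf("'%s': missing Rows/Columns", f))
  bits <- val_us(els[["0028,0100"]]); if (is.null(bits)) bits <- 16L
  if (bits != 16L)
    stop_input(sprintf("'%s': only 16-bit pixel data supported", f))
  signed <- identical(val_us(els[["0028,0103"]]), 1L)
  px_el <- els[["7FE0,0010"]]
  if (is.null(px_el)) stop_input(sprintf("'%s': no pixel data", f))
  stored <- readBin(px_el$bytes, "integer", n = rows * cols, size = 2,
                    signed = TRUE, endian = "little")
  if (!signed) stored <- ifelse(stored < 0, stored + 65536, stored)

  slope_v <- val_ds(els[["0028,1053"]])
  inter_v <- val_ds(els[["0028,1052"]])
  has_rescale <- !is.null(slope_v) && !is.null(inter_v)
  slope <- if (has_rescale) slope_v[1] else 1
  intercept <- if (has_rescale) inter_v[1] else 0

  ipp <- val_ds(els[["0020,0032"]])
  sloc <- val_ds(els[["0020,1041"]])
  z <- NA_real_; z_source <- NA_character_
  if (!is.null(ipp) && length(ipp) >= 3L) {
    z <- ipp[3]; z_source <- "image_position"
  } else if (!is.null(sloc)) {
    z <- sloc[1]; z_source <- "slice_location"
  }
  if (!is.finite(z))
    stop_input(sprintf("'%s': no usable slice position tag", f))

  spacing <- val_ds(els[["0028,0030"]])
  if (is.null(spacing) || length(spacing) < 2L) spacing <- c(1, 1)
  thick <- val_ds(els[["0018,0050"]])
  thick <- if (is.null(thick)) NA_real_ else thick[1]

  # pixel data arrives row-major; fill by column of the transpose
  pixels <- t(matrix(slope * stored + intercept, nrow = cols, ncol = rows))
  list(pixels = pixels, z = z, z_source = z_source, thickness = thick,
       pixel_spacing = spacing, has_rescale = has_rescale,
       series_uid = val_str(els[["0020,000E"]]))
}

parse_meta <- function(bytes, at, end) {
  ts <- NULL
  while (at < end) {
    group <- u16(bytes, at); element <- u16(bytes, at + 2L)
    vr <- rawToChar(bytes[(at + 4L):(at + 5L)])
    if (vr %in% LONG_VRS) {
      len <- u32(bytes, at + 8L); at <- at + 12L
    } else {
      len <- u16(bytes, at + 6L); at <- at + 8L
    }
    if (group == 0x0002L && element == 0x0010L)
      ts <- bytes_to_str(bytes[at:(at + len - 1L)])
    at <- at + len
  }
  list(ts = ts)
}

#' Read a DICOM directory into an image series
#'
#' Reads every parseable single-frame DICOM file in a directory, applies
#' the rescale slope and intercept from each header so the pixel values are
#' in Hounsfield units, sorts the slices by ascending axial position, and
#' infers the reconstruction interval from the median inter-slice spacing.
#'
#' The axial position is taken from the z component of Image Position
#' (Patient) when present, falling back to the Slice Location tag; the
#' source used is reported in the `z_source` attribute of the result.
#' Files missing rescale tags are read with slope 1 / intercept 0 and a
#' warning. Slice spacing may deviate from the median interval by at most
#' 1%; beyond that a spacing error is raised rather than silently
#' resampling.
#'
#' @param path directory containing the DICOM files of one series.
#' @return A [image_series()] object with attribute `z_source`.
#' @export
read_series <- function(path) {
  if (!dir.exists(path)) stop_input(sprintf("'%s' is not a directory", path))
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L)
    stop_input(sprintf("no files found in '%s'", path))
  parsed <- list()
  for (f in files) {
    p <- tryCatch(read_dicom_file(f), ctssp_input_error = function(e) NULL)
    if (!is.null(p)) parsed[[length(parsed) + 1L]] <- p
  }
  if (length(parsed) == 0L)
    stop_input(sprintf("no readable DICOM files in '%s'", path))
  if (length(parsed) < 3L)
    stop_compute(sprintf("only %d readable slice(s) in '%s'; an SSP series needs at least 3",
                         length(parsed), path),
                 "ctssp_truncated_profile")
  uids <- unique(vapply(parsed, function(p) p$series_uid %||% "", character(1)))
  uids <- uids[uids != ""]
  if (length(uids) > 1L)
    stop_ctssp(sprintf("directory '%s' mixes %d different series UIDs", path, length(uids)),
               c("ctssp_ambiguity_error", "ctssp_input_error"))
  if (any(!vapply(parsed, function(p) p$has_rescale, logical(1))))
    warn_ctssp("some files lack rescale slope/intercept tags; assuming slope 1, intercept 0",
               "ctssp_rescale_warning")
  thick <- vapply(parsed, function(p) p$thickness, numeric(1))
  thick <- thick[is.finite(thick)]
  thickness <- if (length(thick)) stats::median(thick) else 1
  slices <- lapply(parsed, function(p)
    slice_image(p$pixels, p$z, thickness, p$pixel_spacing))
  series <- image_series(slices, spacing_tol_frac = 0.01)
  attr(series, "z_source") <- parsed[[1L]]$z_source
  series
}

`%||%` <- function(a, b) if (is.null(a)) b else a
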