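#' Region of interest specification
#'
#' Defines the fixed pixel region summarized on every slice. The ROI is
#' fixed in pixel coordinates and propagated unchanged through the whole
#' series; circle membership uses the pixel-centre-within-radius rule
#' (inclusive).
#'
#' @param shape `"circle"` or `"rectangle"`.
#' @param center ROI centre `(row, col)` in pixels (may be fractional).
#' @param radius circle radius in pixels (circles only).
#' @param size rectangle `(height, width)` in pixels (rectangles only).
#' @param placement `"manual"` or `"auto"`, informational.
#' @return An object of class `ctssp_roi`.
#' @export
roi_spec <- function(shape = c("circle", "rectangle"), center,
                     radius = NULL, size = NULL, placement = "manual") {
  shape <- match.arg(shape)
  if (length(center) != 2L || !is.numeric(center))
    stop_input("'center' must be (row, col) in pixels")
  if (shape == "circle") {
    if (is.null(radius) || radius <= 0)
      stop_input("a circular ROI needs a positive 'radius'")
  } else {
    if (is.null(size) || length(size) != 2L || any(size < 1))
      stop_input("a rectangular ROI needs 'size' = (height, width) >= 1")
    size <- as.integer(round(size))
  }
  structure(list(shape = shape, center = as.numeric(center),
                 radius = radius, size = size, placement = placement),
            class = "ctssp_roi")
}

# logical membership mask for an image of dimension dim = c(rows, cols)
roi_mask <- function(roi, dim) {
  rows <- dim[1L]; cols <- dim[2L]
  if (roi$shape == "circle") {
    r <- roi$center[1L]; c <- roi$center[2L]; rad <- roi$radius
    if (r - rad < 1 || r + rad > rows || c - rad < 1 || c + rad > cols)
      stop_ctssp("ROI extends outside the image bounds",
                 c("ctssp_bounds_error", "ctssp_input_error"))
    rr <- matrix(seq_len(rows), rows, cols)
    cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
    mask <- (rr - r)^2 + (cc - c)^2 <= rad^2 + 1e-9
  } else {
    h <- roi$size[1L]; w <- roi$size[2L]
    r0 <- round(roi$center[1L] - (h - 1) / 2)
    c0 <- round(roi$center[2L] - (w - 1) / 2)
    if (r0 < 1 || c0 < 1 || r0 + h - 1 > rows || c0 + w - 1 > cols)
      stop_ctssp("ROI extends outside the image bounds",
                 c("ctssp_bounds_error", "ctssp_input_error"))
    mask <- matrix(FALSE, rows, cols)
    mask[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- TRUE
  }
  if (!any(mask))
    stop_input("ROI contains no pixels")
  mask
}

#' Standard ROI presets around the test object
#'
#' Four ROI geometries of varying size, shape and placement, used to probe
#' whether the ROI choice affects the measured profile: a small circle
#' (radius 3 px), a large circle (radius 10 px), a small 5x5 square, and a
#' 9x15 rectangle offset from the object by (2, 3) px. Dimensions are
#' package choices; the max-ROI profile is insensitive to them as long as
#' the peak pixel stays inside.
#'
#' @param center `(row, col)` pixel coordinates of the test object.
#' @return Named list of [roi_spec()] objects (`roi1` ... `roi4`).
#' @export
roi_presets <- function(center) {
  list(
    roi1 = roi_spec("circle", center, radius = 3, placement = "auto"),
    roi2 = roi_spec("circle", center, radius = 10, placement = "auto"),
    roi3 = roi_spec("rectangle", center, size = c(5, 5), placement = "auto"),
    roi4 = roi_spec("rectangle", center + c(2, 3), size = c(9, 15),
                    placement = "auto")
  )
}

#' Per-slice ROI statistic
#'
#' Summarizes the ROI on each slice by its mean or maximum HU, producing
#' the raw signal-vs-position vector from which the SSP is built.
#'
#' @param series a [image_series()].
#' @param roi a [roi_spec()].
#' @param statistic `"mean"` or `"max"`.
#' @return Numeric vector of HU values, one per slice (in z order).
#' @export
sample_roi <- function(series, roi, statistic = c("max", "mean")) {
  statistic <- match.arg(statistic)
  mask <- roi_mask(roi, dim(series$slices[[1L]]$pixels))
  fun <- if (statistic == "mean") mean else max
  vapply(series$slices, function(s) fun(s$pixels[mask]), numeric(1))
}

#' Background correction from the outermost slices
#'
#' Subtracts the average of the first and last elements (the outermost
#' slices of the scan range) from every element. Warns when the profile
#' does not appear to have decayed to baseline at the ends of the range —
#' either because the corrected end values stay above 10% of the corrected
#' peak (asymmetric truncation) or because the profile is still changing
#' rapidly at the ends.
#'
#' @param values numeric vector of per-slice HU (length >= 3).
#' @return Corrected vector; attribute `background` holds the subtracted
#'   scalar.
#' @export
background_correct <- function(values) {
  if (length(values) < 3L)
    stop_input("background correction needs at least 3 values")
  n <- length(values)
  bg <- (values[1L] + values[n]) / 2
  out <- values - bg
  peak <- max(out)
  if (peak > 0) {
    ends_high <- max(abs(out[c(1L, n)])) > 0.1 * peak
    steep <- max(abs(out[2L] - out[1L]), abs(out[n] - out[n - 1L])) > 0.05 * peak
    if (ends_high || steep)
      warn_ctssp(paste("profile tails not resolved: scan range may not",
                       "encompass the full slice profile"),
                 "ctssp_truncation_warning")
  }
  attr(out, "background") <- bg
  out
}

#' Peak normalization
#'
#' Divides a vector by its maximum so the peak equals exactly 1.
#'
#' @param values numeric vector with a positive maximum.
#' @return Normalized vector; attribute `norm_factor` holds the divisor.
#' @export
normalize <- function(values) {
  m <- max(values)
  if (!is.finite(m) || m <= 0)
    stop_compute("degenerate signal: maximum is not positive, cannot normalize",
                 "ctssp_degenerate_signal")
  out <- values / m
  attr(out, "norm_factor") <- m
  out
}

#' Build a slice sensitivity profile
#'
#' Composes [sample_roi()], [background_correct()] and [normalize()] and
#' pairs the result with the slice positions: the SSP is the normalized,
#' background-corrected ROI statistic plotted against slice location.
#'
#' @inheritParams sample_roi
#' @return An object of class `ctssp_ssp` with fields `z` (mm), `v`
#'   (dimensionless, peak 1), `statistic`, `background`, `norm_factor`,
#'   `thickness`, `interval`.
#' @export
build_ssp <- function(series, roi, statistic = c("max", "mean")) {
  statistic <- match.arg(statistic)
  raw_vals <- sample_roi(series, roi, statistic)
  corr <- background_correct(raw_vals)
  v <- normalize(corr)
  structure(
    list(z = series$z, v = as.numeric(v), statistic = statistic,
         background = attr(corr, "background"),
         norm_factor = attr(v, "norm_factor"),
         thickness = series$thickness, interval = series$interval),
    class = "ctssp_ssp"
  )
}

#' @export
print.ctssp_ssp <- function(x, ...) {
  cat(sprintf(
    "SSP curve (%s-ROI): %d points, z in [%.3f, %.3f] mm, background %.2f HU, norm %.2f HU\n",
    x$statistic, length(x$z), min(x$z), max(x$z), x$background, x$norm_factor))
  invisible(x)
}

#' @export
as.data.frame.ctssp_ssp <- function(x, ...) {
  data.frame(z = x$z, value = x$v)
}

#' Automatic ROI placement on the hottest pixel
#'
#' Centres an ROI on the pixel with the global maximum HU across the whole
#' series — the test-object location in a point-response phantom scan. If
#' the maximum is tied across pixels that are not neighbours (e.g. a blank
#' series), an ambiguity warning is raised and the first tied pixel in
#' scan order is used; for a fully blank series the ROI falls back to the
#' image centre. The centre is clamped so the ROI fits inside the image.
#'
#' @param series a [image_series()].
#' @param shape,radius,size ROI geometry, as in [roi_spec()].
#' @return A [roi_spec()] with `placement = "auto"`.
#' @export
auto_place_roi <- function(series, shape = "circle", radius = 3, size = c(5, 5)) {
  arr <- series_array(series)
  d <- dim(arr)
  gmax <- max(arr)
  tol <- 1e-9 * max(1, abs(gmax))
  hits <- which(arr >= gmax - tol)
  rc <- arrayInd(hits, d)[, 1:2, drop = FALSE]
  rc <- unique(rc)
  if (nrow(rc) == d[1L] * d[2L]) {
    warn_ctssp("no distinct maximum found (blank series); centering ROI on the image",
               "ctssp_ambiguity_warning")
    center <- (d[1:2] + 1) / 2
  } else {
    spread <- apply(rc, 2L, function(x) diff(range(x)))
    if (nrow(rc) > 1L && any(spread > 1)) {
      warn_ctssp("multiple disconnected maxima; using the first in scan order",
                 "ctssp_ambiguity_warning")
    }
    center <- as.numeric(rc[1L, ])
  }
  half <- if (shape == "circle") c(radius, radius) else (size - 1) / 2
  center[1L] <- min(max(center[1L], 1 + half[1L]), d[1L] - half[1L])
  center[2L] <- min(max(center[2L], 1 + half[2L]), d[2L] - half[2L])
  roi_spec(shape, center, radius = radius, size = size, placement = "auto")
}

#' Export an SSP curve as CSV
#'
#' @param ssp a `ctssp_ssp` object.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_ssp_csv <- function(ssp, path) {
  utils::write.csv(as.data.frame(ssp), path, row.names = FALSE)
  invisible(path)
}
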