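#' Single reconstructed CT slice
#'
#' A `slice_image` holds one reconstructed axial CT image in Hounsfield
#' units together with its axial position. The axial coordinate is signed
#' millimetres with superior positive, so a slice at S3 has `z = 3` and a
#' slice at I3 has `z = -3`.
#'
#' @param pixels numeric matrix of HU values, indexed `[row, col]`.
#' @param z axial slice position in mm (signed, superior positive).
#' @param thickness nominal slice thickness T in mm; must be positive.
#' @param pixel_spacing in-plane pixel spacing `(row, col)` in mm; a scalar
#'   is recycled to both directions.
#'
#' @return An object of class `ctssp_slice`.
#' @export
slice_image <- function(pixels, z, thickness, pixel_spacing = c(0.5, 0.5)) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L)
    stop_input("'pixels' must be a non-empty numeric matrix")
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z))
    stop_input("'z' must be a single finite number (mm)")
  if (!is.numeric(thickness) || length(thickness) != 1L || thickness <= 0)
    stop_input("'thickness' must be a single positive number (mm)")
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (length(pixel_spacing) != 2L || any(pixel_spacing <= 0))
    stop_input("'pixel_spacing' must be two positive numbers (mm)")
  structure(
    list(pixels = pixels, z = as.numeric(z),
         thickness = as.numeric(thickness),
         pixel_spacing = as.numeric(pixel_spacing)),
    class = "ctssp_slice"
  )
}

#' Ordered stack of overlapping CT slices
#'
#' An `image_series` is the in-memory form of a phantom scan: slices sorted
#' by ascending axial position on a (near-)uniform grid. The slice-location
#' vector is the 1-D axis against which the slice sensitivity profile is
#' plotted.
#'
#' @param slices list of [slice_image()] objects (at least 3).
#' @param acquisition_meta named list of informational acquisition tags
#'   (kVp, mAs, pitch, scan FOV, ...). Carried along, never used in
#'   computation.
#' @param spacing_tol_frac allowed fractional deviation of each inter-slice
#'   gap from the median interval. The default `0` enforces a uniform grid
#'   to within 1e-6 mm; [read_series()] relaxes this to 1% to absorb
#'   header rounding.
#'
#' @return An object of class `ctssp_series` with fields `slices`,
#'   `z` (positions), `interval` (median spacing, mm), `thickness`,
#'   `acquisition_meta`.
#' @export
image_series <- function(slices, acquisition_meta = list(),
                         spacing_tol_frac = 0) {
  if (!is.list(slices) || length(slices) < 3L)
    stop_input("an image series needs at least 3 slices")
  ok <- vapply(slices, inherits, logical(1), what = "ctssp_slice")
  if (!all(ok)) stop_input("all elements of 'slices' must be slice_image objects")
  z <- vapply(slices, function(s) s$z, numeric(1))
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]
  if (any(diff(z) <= 0))
    stop_input("slice positions must be strictly monotone (duplicate z found)")
  dims <- vapply(slices, function(s) dim(s$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_input("all slices must share the same pixel dimensions")
  gaps <- diff(z)
  interval <- stats::median(gaps)
  tol <- max(1e-6, spacing_tol_frac * interval)
  if (any(abs(gaps - interval) > tol))
    stop_ctssp(
      sprintf("non-uniform slice spacing: max deviation %.3g mm exceeds tolerance %.3g mm",
              max(abs(gaps - interval)), tol),
      c("ctssp_spacing_error", "ctssp_input_error"))
  structure(
    list(slices = slices, z = z, interval = interval,
         thickness = slices[[1L]]$thickness,
         acquisition_meta = acquisition_meta),
    class = "ctssp_series"
  )
}

#' @export
print.ctssp_series <- function(x, ...) {
  d <- dim(x$slices[[1L]]$pixels)
  cat(sprintf(
    "CT image series: %d slices of %dx%d px, z in [%.3f, %.3f] mm, interval %.4f mm, thickness %.3f mm\n",
    length(x$slices), d[1L], d[2L], min(x$z), max(x$z), x$interval,
    x$thickness))
  invisible(x)
}

#' @export
print.ctssp_slice <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("CT slice: %dx%d px at z = %.3f mm (thickness %.3f mm)\n",
              d[1L], d[2L], x$z, x$thickness))
  invisible(x)
}

# stack all pixel data into a row x col x slice array
series_array <- function(series) {
  d <- dim(series$slices[[1L]]$pixels)
  arr <- array(0, dim = c(d, length(series$slices)))
  for (i in seq_along(series$slices)) arr[, , i] <- series$slices[[i]]$pixels
  arr
}
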