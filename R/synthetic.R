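#' Simulation configuration for a synthetic point-response phantom series
#'
#' Describes the ground truth and acquisition grid for a simulated
#' overlapping-slice scan of a point object (bead/disc). The axial signal
#' of the object follows a known profile (Gaussian by default) with an
#' exact, user-chosen FWHM — the quantity the analysis pipeline must
#' recover. Slices are placed at interval `thickness / interval_divisor`
#' over `±range_multiplier * thickness`, mirroring the overlapping
#' reconstruction used to sample an SSP (divisor 10 over ±5 slice widths
#' gives the canonical 101-image series).
#'
#' The simulator models the reconstructed image stack directly, not
#' helical projection physics: acquisition factors (pitch, collimation,
#' FOV) are representable only through `true_fwhm` and `noise_sd`, and are
#' carried as inert metadata.
#'
#' @param true_fwhm ground-truth axial FWHM in mm.
#' @param thickness nominal slice thickness T in mm.
#' @param profile axial profile shape: `"gaussian"` (default) or
#'   `"triangular"`; both have FWHM exactly `true_fwhm`.
#' @param interval_divisor k: slice interval is T/k (default 10).
#' @param range_multiplier m: grid spans ±m·T (default 5).
#' @param object_z axial position of the point object in mm (default 0,
#'   i.e. isocenter S0).
#' @param object_xy `(row, col)` pixel position of the object; default
#'   image centre.
#' @param peak_hu HU amplitude of the object at focus (default 1000, a
#'   high-attenuation bead over background).
#' @param background_hu background HU (default 0).
#' @param inplane_sigma0 in-plane Gaussian blur sigma at focus, mm
#'   (default 0.4, bead-scale blur).
#' @param inplane_spread_coeff c >= 0: in-plane sigma grows as
#'   `sigma0 * (1 + c * |dz| / true_fwhm)` away from focus. 0 (default)
#'   keeps the in-plane shape z-independent, making mean-ROI and max-ROI
#'   profiles identical; c > 0 broadens mean-ROI profiles.
#' @param noise_sd additive Gaussian noise sd in HU (default 0).
#' @param image_size image side in pixels (default 64).
#' @param pixel_spacing in-plane pixel spacing in mm (default 0.5).
#' @param seed integer RNG seed for the noise (default NULL: leave RNG
#'   state alone).
#' @param acquisition_meta informational tags (default kVp 120, 325 mAs,
#'   pitch 0.969 — never used computationally).
#' @return An object of class `ctssp_simconfig`.
#' @export
sim_config <- function(true_fwhm, thickness,
                       profile = c("gaussian", "triangular"),
                       interval_divisor = 10, range_multiplier = 5,
                       object_z = 0, object_xy = NULL,
                       peak_hu = 1000, background_hu = 0,
                       inplane_sigma0 = 0.4, inplane_spread_coeff = 0,
                       noise_sd = 0, image_size = 64, pixel_spacing = 0.5,
                       seed = NULL,
                       acquisition_meta = list(kVp = 120, mAs = 325,
                                               pitch = 0.969)) {
  profile <- match.arg(profile)
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop_input(sprintf("'%s' must be a single positive number", nm))
  }
  chk_pos(true_fwhm, "true_fwhm"); chk_pos(thickness, "thickness")
  chk_pos(interval_divisor, "interval_divisor")
  chk_pos(range_multiplier, "range_multiplier")
  chk_pos(peak_hu, "peak_hu"); chk_pos(inplane_sigma0, "inplane_sigma0")
  chk_pos(pixel_spacing, "pixel_spacing")
  chk_pos(image_size, "image_size")
  if (inplane_spread_coeff < 0 || noise_sd < 0)
    stop_input("'inplane_spread_coeff' and 'noise_sd' must be >= 0")
  image_size <- as.integer(image_size)
  # default object position on a pixel centre so the 2-D blur peaks at 1
  if (is.null(object_xy)) object_xy <- rep(ceiling(image_size / 2), 2L)
  if (length(object_xy) != 2L || any(object_xy < 1) ||
      any(object_xy > image_size))
    stop_input("'object_xy' must lie inside the image")
  structure(
    list(true_fwhm = true_fwhm, thickness = thickness, profile = profile,
         interval_divisor = interval_divisor,
         range_multiplier = range_multiplier,
         object_z = object_z, object_xy = as.numeric(object_xy),
         peak_hu = peak_hu, background_hu = background_hu,
         inplane_sigma0 = inplane_sigma0,
         inplane_spread_coeff = inplane_spread_coeff,
         noise_sd = noise_sd, image_size = image_size,
         pixel_spacing = pixel_spacing, seed = seed,
         acquisition_meta = acquisition_meta),
    class = "ctssp_simconfig"
  )
}

#' Number of slice positions on the reconstruction grid
#'
#' A grid spanning ±m slice thicknesses at interval thickness/k has
#' `2*m*k + 1` positions, endpoints inclusive. A non-integral step count
#' is rounded up so the grid still covers the full range (divisors 10, 5
#' and 2.5 over ±5 slice widths give 101, 51 and 26 positions).
#'
#' @param m range multiplier (grid spans ±m·T).
#' @param k interval divisor (spacing T/k).
#' @return Integer number of slice positions.
#' @export
n_slice_positions <- function(m, k) {
  if (m <= 0 || k <= 0) stop_input("'m' and 'k' must be positive")
  as.integer(ceiling(2 * m * k - 1e-9)) + 1L
}

# the slice-position grid itself, centred on 0
slice_grid <- function(thickness, k, m) {
  n <- n_slice_positions(m, k)
  -m * thickness + (seq_len(n) - 1L) * thickness / k
}

#' Ground-truth axial weight of the simulated point object
#'
#' The dimensionless axial signal at offset `dz` from the object:
#' `gaussian` gives \eqn{\exp(-dz^2/(2\sigma_z^2))} with
#' \eqn{\sigma_z = FWHM / (2\sqrt{2\ln 2})}; `triangular` gives
#' \eqn{\max(0, 1 - |dz|/FWHM)}. Both equal 0.5 at `dz = FWHM/2` by
#' construction.
#'
#' @param dz axial offset(s) from the object position, mm.
#' @param config a [sim_config()].
#' @return Weight(s) in `[0, 1]`.
#' @export
axial_weight <- function(dz, config) {
  if (config$profile == "gaussian") {
    sz <- config$true_fwhm / GAUSS_FWHM_FACTOR
    exp(-dz^2 / (2 * sz^2))
  } else {
    pmax(0, 1 - abs(dz) / config$true_fwhm)
  }
}

#' Generate a synthetic overlapping-slice phantom series
#'
#' For each grid position z the slice image is
#' \deqn{background + peak \cdot w(z - z_0) \cdot G_{2D}(\sigma_{xy}(z - z_0)) + N(0, noise\_sd)}
#' where w is [axial_weight()] and \eqn{G_{2D}} is a unit-peak 2-D
#' Gaussian at the object's pixel position with
#' \eqn{\sigma_{xy}(dz) = \sigma_0 (1 + c\,|dz|/FWHM)}. With a fixed seed
#' the output is bit-reproducible.
#'
#' @param config a [sim_config()].
#' @return A [image_series()]; attribute `truth` carries the config.
#' @export
generate_series <- function(config) {
  if (!inherits(config, "ctssp_simconfig"))
    stop_input("'config' must be a sim_config object")
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  z <- slice_grid(config$thickness, config$interval_divisor,
                  config$range_multiplier)
  n <- config$image_size
  ps <- config$pixel_spacing
  # squared in-plane distance (mm^2) of every pixel centre from the object
  dr <- (seq_len(n) - config$object_xy[1L]) * ps
  dc <- (seq_len(n) - config$object_xy[2L]) * ps
  r2 <- outer(dr^2, dc^2, `+`)
  slices <- vector("list", length(z))
  for (i in seq_along(z)) {
    dz <- z[i] - config$object_z
    sxy <- config$inplane_sigma0 *
      (1 + config$inplane_spread_coeff * abs(dz) / config$true_fwhm)
    img <- config$background_hu +
      config$peak_hu * axial_weight(dz, config) * exp(-r2 / (2 * sxy^2))
    if (config$noise_sd > 0)
      img <- img + matrix(stats::rnorm(n * n, 0, config$noise_sd), n, n)
    slices[[i]] <- slice_image(img, z[i], config$thickness, ps)
  }
  series <- image_series(slices, acquisition_meta = config$acquisition_meta)
  attr(series, "truth") <- config
  series
}
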