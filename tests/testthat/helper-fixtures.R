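# shared fixtures: tiny hand-built series and canonical sim settings

# series whose slice i is a constant image of value vals[i], plus an
# optional hot pixel at (hot_r, hot_c) with value hot[i]
make_flat_series <- function(vals, z = seq_along(vals), nrow = 8, ncol = 8,
                             hot = NULL, hot_r = 4, hot_c = 5,
                             thickness = 1) {
  slices <- lapply(seq_along(vals), function(i) {
    m <- matrix(vals[i], nrow, ncol)
    if (!is.null(hot)) m[hot_r, hot_c] <- hot[i]
    slice_image(m, z[i], thickness, c(1, 1))
  })
  image_series(slices)
}

# the four nominal thickness -> specified FWHM pairs used throughout
SPEC_PAIRS <- data.frame(
  thickness = c(0.625, 1.25, 2.5, 5.0),
  fwhm = c(0.98, 1.38, 2.88, 6.00)
)

# canonical noise level (HU) for Monte-Carlo tests: bead-phantom head-scan
# scale noise against a 1000 HU object
MC_NOISE_SD <- 5

# brute-force crossing oracle: linear interpolation on a grid 1000x denser
# than the samples, scanning outward from the peak, then interpolating
# between the bracketing dense neighbours
oracle_crossing <- function(z, v, level, side) {
  dense <- stats::approx(z, v, n = (length(z) - 1L) * 1000L + 1L)
  j <- which.max(dense$y)
  idx <- if (side == "left") seq(j - 1L, 1L) else seq(j + 1L, length(dense$x))
  for (i in idx) {
    if (dense$y[i] == level) return(dense$x[i])
    if (dense$y[i] < level) {
      inner <- if (side == "left") i + 1L else i - 1L
      return(dense$x[i] + (level - dense$y[i]) /
               (dense$y[inner] - dense$y[i]) * (dense$x[inner] - dense$x[i]))
    }
  }
  stop("oracle found no crossing")
}

# exact Gaussian curve sampled on a grid (no container overhead)
gauss_curve <- function(sigma = 1, interval = 0.1, halfwidth = 5,
                        mu = 0, amp = 1, baseline = 0) {
  z <- seq(-halfwidth, halfwidth, by = interval) + mu
  list(z = z, v = amp * exp(-(z - mu)^2 / (2 * sigma^2)) + baseline)
}
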