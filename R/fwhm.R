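GAUSS_FWHM_FACTOR <- 2 * sqrt(2 * log(2)) # FWHM = 2.3548... * sigma

fwhm_result <- function(method, fwhm, left_cross, right_cross,
                        half_levels, fit = NULL) {
  structure(
    list(method = method, fwhm = fwhm, left_cross = left_cross,
         right_cross = right_cross, half_levels = half_levels, fit = fit),
    class = "ctssp_fwhm"
  )
}

#' @export
print.ctssp_fwhm <- function(x, ...) {
  cat(sprintf("FWHM [%s]: %.4f mm (crossings %.4f / %.4f mm)\n",
              x$method, x$fwhm, x$left_cross, x$right_cross))
  if (!is.null(x$fit))
    cat(sprintf("  fit: A=%.4f mu=%.4f sigma=%.4f b=%.4f (residual norm %.3g)\n",
                x$fit$A, x$fit$mu, x$fit$sigma, x$fit$b, x$fit$resid_norm))
  invisible(x)
}

# curve accessor: accepts a ctssp_ssp or a list(z, v)
curve_zv <- function(curve) {
  if (inherits(curve, "ctssp_ssp")) list(z = curve$z, v = curve$v)
  else if (is.list(curve) && all(c("z", "v") %in% names(curve)))
    list(z = as.numeric(curve$z), v = as.numeric(curve$v))
  else stop_input("'curve' must be an SSP curve or a list with z and v")
}

check_peak <- function(z, v) {
  n <- length(z)
  if (n < 5L) stop_input("FWHM estimation needs at least 5 samples")
  j <- which.max(v)
  if (j == 1L || j == n)
    stop_compute("peak lies at the end of the scan range (truncated profile)",
                 "ctssp_truncated_profile")
  j
}

# first half-level crossing scanning outward from the peak on one side;
# exact ties at the level take that sample's position
cross_outward <- function(z, v, j, level, side) {
  idx <- if (side == "left") seq(j - 1L, 1L) else seq(j + 1L, length(z))
  eps <- 1e-12 * max(abs(v))
  for (i in idx) {
    if (abs(v[i] - level) <= eps) return(z[i])
    if (v[i] < level) {
      inner <- if (side == "left") i + 1L else i - 1L
      # linear interpolation between the bracketing samples
      return(z[i] + (level - v[i]) / (v[inner] - v[i]) * (z[inner] - z[i]))
    }
  }
  stop_compute(sprintf("no half-maximum crossing found on the %s side", side),
               "ctssp_range_error")
}

#' FWHM by linear interpolation
#'
#' Estimates the full width at half maximum of an SSP curve from
#' half-level crossings located by linear interpolation between samples.
#' The half level on side s is \eqn{h_s = m_s + (peak - m_s)/2}, where
#' \eqn{m_s} is the minimum of that side of the curve; after background
#' correction these minima are near zero so the level is near half the
#' peak. Three variants differ in which side defines the level:
#' \describe{
#'   \item{left}{the left side's level is used for both crossings}
#'   \item{right}{the right side's level is used for both crossings}
#'   \item{two_sided}{each side's own level locates its own crossing}
#' }
#' Crossings are searched outward from the peak, taking the first
#' bracketing pair on each side (robust to tail noise).
#'
#' @param curve a [build_ssp()] curve (or any list with `z`, `v`).
#' @param mode `"two_sided"`, `"left"` or `"right"`.
#' @param reflect for modes `left`/`right` only: instead of locating both
#'   crossings at the single level, locate only that side's crossing and
#'   mirror it about the peak position (`fwhm = 2 |z_peak - crossing|`).
#'   Default `FALSE` (both crossings at the one level).
#' @return A `ctssp_fwhm` result with `fwhm = right_cross - left_cross`.
#' @export
fwhm_interp <- function(curve, mode = c("two_sided", "left", "right"),
                        reflect = FALSE) {
  mode <- match.arg(mode)
  zv <- curve_zv(curve); z <- zv$z; v <- zv$v
  j <- check_peak(z, v)
  peak <- v[j]
  m_left <- min(v[1:j]); m_right <- min(v[j:length(v)])
  h_left <- m_left + 0.5 * (peak - m_left)
  h_right <- m_right + 0.5 * (peak - m_right)
  levels <- switch(mode,
    left = c(h_left, h_left),
    right = c(h_right, h_right),
    two_sided = c(h_left, h_right))
  if (reflect && mode != "two_sided") {
    side <- mode
    cr <- cross_outward(z, v, j, levels[1L], side)
    half <- abs(z[j] - cr)
    lc <- z[j] - half; rc <- z[j] + half
  } else {
    lc <- cross_outward(z, v, j, levels[1L], "left")
    rc <- cross_outward(z, v, j, levels[2L], "right")
  }
  if (rc - lc <= 0)
    stop_compute("non-positive FWHM from crossings", "ctssp_range_error")
  fwhm_result(mode, rc - lc, lc, rc, half_levels = levels)
}

#' FWHM by Gaussian curve fitting
#'
#' Fits \eqn{A \exp(-(z-\mu)^2 / (2\sigma^2)) + b} to the SSP by nonlinear
#' least squares and reports \eqn{FWHM = 2\sqrt{2\ln 2}\,\sigma}. Slice
#' sensitivity profiles of helical CT are well approximated by Gaussians,
#' and the fit uses all samples rather than two crossings, which buys
#' precision under noise.
#'
#' Initialization: \eqn{\mu} at the peak sample, \eqn{A} the peak value,
#' \eqn{\sigma} from the two-sided interpolated FWHM, \eqn{b = 0}. The
#' baseline is fitted by default but constrained to \eqn{|b| \le 0.2}
#' since curves arrive background-corrected; set `fit_baseline = FALSE`
#' to pin it at zero.
#'
#' @param curve a [build_ssp()] curve (or any list with `z`, `v`).
#' @param fit_baseline fit the additive baseline term? Default `TRUE`.
#' @return A `ctssp_fwhm` result; `fit` holds `A`, `mu`, `sigma`, `b` and
#'   the residual norm, and the crossings are those of the fitted curve.
#' @export
fwhm_gauss <- function(curve, fit_baseline = TRUE) {
  zv <- curve_zv(curve); z <- zv$z; v <- zv$v
  j <- check_peak(z, v)
  sigma0 <- tryCatch(
    fwhm_interp(curve, "two_sided")$fwhm / GAUSS_FWHM_FACTOR,
    ctssp_error = function(e) diff(range(z)) / 8)
  # bounded least squares via L-BFGS-B with analytic gradient; par is
  # (A, mu, sigma[, b])
  model <- function(p) {
    g <- exp(-(z - p[2L])^2 / (2 * p[3L]^2))
    p[1L] * g + if (fit_baseline) p[4L] else 0
  }
  ssr <- function(p) sum((model(p) - v)^2)
  ssr_grad <- function(p) {
    dz_ <- z - p[2L]
    g <- exp(-dz_^2 / (2 * p[3L]^2))
    r <- p[1L] * g + (if (fit_baseline) p[4L] else 0) - v
    gr <- c(2 * sum(r * g),
            2 * sum(r * p[1L] * g * dz_ / p[3L]^2),
            2 * sum(r * p[1L] * g * dz_^2 / p[3L]^3))
    if (fit_baseline) gr <- c(gr, 2 * sum(r))
    gr
  }
  start <- c(v[j], z[j], sigma0)
  lower <- c(1e-8, min(z), 1e-6)
  upper <- c(Inf, max(z), diff(range(z)))
  if (fit_baseline) {
    # baseline bounded: curves are background-corrected
    start <- c(start, 0)
    lower <- c(lower, -0.2 * v[j])
    upper <- c(upper, 0.2 * v[j])
  }
  fit <- stats::optim(start, ssr, gr = ssr_grad, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 500, factr = 1e4))
  if (fit$convergence != 0L)
    stop_compute(sprintf("Gaussian fit failed to converge: %s (code %d)",
                         fit$message, fit$convergence),
                 "ctssp_fit_error")
  cf <- c(A = fit$par[1L], mu = fit$par[2L], sigma = fit$par[3L],
          b = if (fit_baseline) fit$par[4L] else 0)
  sigma <- unname(cf[["sigma"]])
  b <- unname(cf[["b"]])
  interval <- stats::median(diff(z))
  if (sigma < interval / 2)
    warn_ctssp(sprintf("fitted sigma (%.4g mm) below half the sampling interval: profile under-resolved",
                       sigma),
               "ctssp_underresolved_warning")
  fw <- GAUSS_FWHM_FACTOR * sigma
  mu <- unname(cf[["mu"]])
  fwhm_result("gaussian", fw, mu - fw / 2, mu + fw / 2,
              half_levels = rep(b + unname(cf[["A"]]) / 2, 2L),
              fit = list(A = unname(cf[["A"]]), mu = mu, sigma = sigma,
                         b = b, resid_norm = sqrt(fit$value)))
}

#' Run all four FWHM methods on one curve
#'
#' @inheritParams fwhm_gauss
#' @param methods subset of `"left"`, `"right"`, `"two_sided"`,
#'   `"gaussian"`.
#' @return Named list of `ctssp_fwhm` results.
#' @export
fwhm_all <- function(curve, methods = c("left", "right", "two_sided", "gaussian"),
                     fit_baseline = TRUE) {
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list()
  for (m in methods) {
    out[[m]] <- if (m == "gaussian") fwhm_gauss(curve, fit_baseline)
                else fwhm_interp(curve, m)
  }
  out
}

#' Flatten FWHM results to a data frame
#'
#' @param results list of `ctssp_fwhm` (as from [fwhm_all()]).
#' @return data.frame with one row per method: `method`, `fwhm_mm`,
#'   `left_cross_mm`, `right_cross_mm`, and fit parameters (NA for the
#'   interpolation methods).
#' @export
fwhm_table <- function(results) {
  if (inherits(results, "ctssp_fwhm")) results <- list(results)
  rows <- lapply(results, function(r) {
    data.frame(method = r$method, fwhm_mm = r$fwhm,
               left_cross_mm = r$left_cross, right_cross_mm = r$right_cross,
               fit_A = if (is.null(r$fit)) NA_real_ else r$fit$A,
               fit_mu = if (is.null(r$fit)) NA_real_ else r$fit$mu,
               fit_sigma = if (is.null(r$fit)) NA_real_ else r$fit$sigma,
               fit_b = if (is.null(r$fit)) NA_real_ else r$fit$b)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
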