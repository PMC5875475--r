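#' Manufacturer slice-thickness specification table
#'
#' Maps nominal slice thickness (mm) to the manufacturer-specified SSP
#' FWHM (mm), the gold standard for percent-error comparison. Defaults are
#' the published values for a 64-row scanner's 0.625/1.25/2.5/5.0 mm
#' reconstructions. Effective slice width always meets or exceeds the
#' nominal thickness.
#'
#' @param values named numeric vector: names are nominal thicknesses (mm),
#'   values the specified FWHM (mm).
#' @return An object of class `ctssp_spec_table`.
#' @export
spec_table <- function(values = c("0.625" = 0.98, "1.25" = 1.38,
                                  "2.5" = 2.88, "5" = 6.00)) {
  thick <- as.numeric(names(values))
  if (any(is.na(thick)) || any(values <= 0))
    stop_input("spec table needs positive FWHM values keyed by numeric thickness")
  if (any(values < thick - 1e-9))
    stop_input("specified FWHM cannot be below the nominal thickness")
  structure(as.numeric(values), names = names(values),
            class = "ctssp_spec_table")
}

#' Look up the specified FWHM for a nominal thickness
#'
#' @param specs a [spec_table()].
#' @param thickness nominal slice thickness in mm.
#' @return Specified FWHM in mm.
#' @export
spec_lookup <- function(specs, thickness) {
  thick <- as.numeric(names(specs))
  i <- which(abs(thick - thickness) < 1e-9)
  if (length(i) != 1L)
    stop_input(sprintf("no manufacturer specification for thickness %g mm", thickness))
  unname(specs[[i]])
}

#' Percent error against a specification
#'
#' \eqn{100 |measured - spec| / spec}; scale-invariant in the sense that
#' scaling both arguments by the same positive constant leaves it
#' unchanged.
#'
#' @param measured measured value(s), mm.
#' @param spec specified value(s), mm; must be positive.
#' @return Percent error(s) on the 0-100 scale.
#' @export
percent_error <- function(measured, spec) {
  if (any(spec <= 0)) stop_input("'spec' must be positive")
  100 * abs(measured - spec) / spec
}

#' One-sample z-test against a specification
#'
#' \eqn{z = (\bar x - spec) / (s/\sqrt n)} with a two-sided p-value from
#' the standard normal. Used to test whether repeated FWHM measurements
#' differ from the manufacturer's value.
#'
#' @param measurements numeric vector, length >= 2.
#' @param spec reference value.
#' @return list with `z`, `p`, `n`, `mean`, `sd`.
#' @export
one_sample_z <- function(measurements, spec) {
  n <- length(measurements)
  if (n < 2L) stop_input("one_sample_z needs at least 2 measurements")
  s <- stats::sd(measurements)
  if (!is.finite(s) || s <= 0)
    stop_compute("zero standard deviation: z statistic undefined",
                 "ctssp_degenerate_variance")
  m <- mean(measurements)
  z <- (m - spec) / (s / sqrt(n))
  list(z = z, p = 2 * stats::pnorm(-abs(z)), n = n, mean = m, sd = s)
}

#' Two-sample (Welch) z-test
#'
#' \eqn{z = (\bar x_A - \bar x_B) / \sqrt{s_A^2/n_A + s_B^2/n_B}},
#' two-sided p from the standard normal. Used to compare FWHM sets, e.g.
#' mean-ROI vs max-ROI profiles.
#'
#' @param a,b numeric vectors, each length >= 2.
#' @return list with `z`, `p`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
two_sample_z <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop_input("two_sample_z needs at least 2 measurements per group")
  va <- stats::var(a); vb <- stats::var(b)
  se <- sqrt(va / length(a) + vb / length(b))
  if (!is.finite(se) || se <= 0)
    stop_compute("both groups have zero variance: z statistic undefined",
                 "ctssp_degenerate_variance")
  z <- (mean(a) - mean(b)) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)),
       mean_a = mean(a), mean_b = mean(b),
       n_a = length(a), n_b = length(b))
}

#' Aggregate repeated FWHM measurements into a comparison report
#'
#' Groups repeated measurements by condition and nominal thickness and,
#' per group, reports mean and sd of the FWHM, error (mean - spec),
#' percent error of the mean, and a one-sample z-test against the
#' specification (NA when sd is zero, e.g. identical repeats). The grand
#' mean of the per-group percent errors is attached as attribute
#' `grand_mean_percent_error`.
#'
#' @param measurements data.frame with columns `condition`, `thickness`
#'   (mm) and `fwhm` (mm), one row per repeat.
#' @param specs a [spec_table()].
#' @param alpha significance level for the `significant` flag (0.05).
#' @return data.frame of class `ctssp_report`, one row per
#'   condition-thickness group.
#' @export
aggregate_report <- function(measurements, specs = spec_table(), alpha = 0.05) {
  need <- c("condition", "thickness", "fwhm")
  if (!is.data.frame(measurements) || !all(need %in% names(measurements)))
    stop_input("'measurements' must have columns condition, thickness, fwhm")
  if (nrow(measurements) == 0L) stop_input("no measurements to aggregate")
  key <- interaction(measurements$condition, measurements$thickness,
                     drop = TRUE, lex.order = TRUE)
  groups <- split(measurements, key)
  rows <- lapply(groups, function(g) {
    spec <- spec_lookup(specs, g$thickness[1L])
    n <- nrow(g)
    m <- mean(g$fwhm)
    s <- if (n >= 2L) stats::sd(g$fwhm) else 0
    zt <- if (n >= 2L && s > 0) one_sample_z(g$fwhm, spec)
          else list(z = NA_real_, p = NA_real_)
    data.frame(condition = as.character(g$condition[1L]),
               thickness = g$thickness[1L], spec = spec, n = n,
               mean_fwhm = m, sd = s, error = m - spec,
               percent_error = percent_error(m, spec),
               z = zt$z, p = zt$p,
               significant = !is.na(zt$p) & zt$p < alpha)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$condition, out$thickness), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "grand_mean_percent_error") <- mean(out$percent_error)
  class(out) <- c("ctssp_report", "data.frame")
  out
}

#' Write a comparison report as CSV
#'
#' Percent errors are written to one decimal place (matching QA report
#' convention); all other columns keep full precision. Output bytes are a
#' pure function of the report contents.
#'
#' @param report a [aggregate_report()] result.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_report_csv <- function(report, path) {
  out <- as.data.frame(report)
  out$percent_error <- sprintf("%.1f", out$percent_error)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
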