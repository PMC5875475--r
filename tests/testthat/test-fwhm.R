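test_that("symmetric triangle gives FWHM 2.0 for every mode", {
  curve <- list(z = c(-2, -1, 0, 1, 2), v = c(0, 0.5, 1, 0.5, 0))
  for (mode in c("left", "right", "two_sided")) {
    r <- fwhm_interp(curve, mode)
    expect_equal(r$left_cross, -1)
    expect_equal(r$right_cross, 1)
    expect_equal(r$fwhm, 2)
  }
})

test_that("asymmetric curve: per-side levels and single-level modes (hand oracle)", {
  # left branch [0, 0.5, 1], right branch [1, 0.6, 0.2]
  curve <- list(z = c(-2, -1, 0, 1, 2), v = c(0, 0.5, 1, 0.6, 0.2))
  ts <- fwhm_interp(curve, "two_sided")
  # left min 0 -> level 0.5, exact tie at z = -1; right min 0.2 -> level 0.6,
  # exact tie at z = +1
  expect_equal(ts$half_levels, c(0.5, 0.6))
  expect_equal(ts$left_cross, -1)
  expect_equal(ts$right_cross, 1)
  expect_equal(ts$fwhm, 2)
  # left-based: level 0.5 applied to BOTH sides; right crossing interpolates
  # between (1, 0.6) and (2, 0.2): z = 1.25
  lb <- fwhm_interp(curve, "left")
  expect_equal(lb$half_levels, c(0.5, 0.5))
  expect_equal(lb$right_cross, 1.25)
  expect_equal(lb$fwhm, 2.25)
  # right-based: level 0.6 applied to both; left crossing between (-1, 0.5)
  # and (0, 1): z = -0.8
  rb <- fwhm_interp(curve, "right")
  expect_equal(rb$left_cross, -0.8)
  expect_equal(rb$fwhm, 1.8)
  # reflect variant mirrors one side about the peak
  lr <- fwhm_interp(curve, "left", reflect = TRUE)
  expect_equal(lr$fwhm, 2)
  rr <- fwhm_interp(curve, "right", reflect = TRUE)
  expect_equal(rr$fwhm, 2)
})

test_that("noise-free Gaussian: interpolation within 0.5%, fit exact", {
  true_fwhm <- ctssp:::GAUSS_FWHM_FACTOR # sigma = 1 -> 2.3548 mm
  g <- gauss_curve(sigma = 1, interval = 0.1)
  for (mode in c("left", "right", "two_sided")) {
    expect_equal(fwhm_interp(g, mode)$fwhm, true_fwhm, tolerance = 0.005)
  }
  r <- fwhm_gauss(g)
  expect_equal(r$fwhm, true_fwhm, tolerance = 1e-6)
  expect_equal(r$fit$sigma, 1, tolerance = 1e-6)
  expect_lt(r$fit$resid_norm, 1e-6)
  # no-baseline variant identical on clean data
  expect_equal(fwhm_gauss(g, fit_baseline = FALSE)$fwhm, r$fwhm,
               tolerance = 1e-6)
})

test_that("interpolated crossings match the dense-grid brute-force oracle", {
  set.seed(42)
  for (rep in 1:20) {
    sigma <- runif(1, 0.5, 3)
    g <- gauss_curve(sigma = sigma, interval = 0.1 * sigma,
                     halfwidth = 5 * sigma, mu = runif(1, -1, 1))
    g$v <- g$v + rnorm(length(g$v), 0, 0.01)
    g$v <- g$v / max(g$v)
    r <- tryCatch(fwhm_interp(g, "two_sided"),
                  ctssp_compute_error = function(e) NULL)
    if (is.null(r)) next
    expect_equal(r$left_cross,
                 oracle_crossing(g$z, g$v, r$half_levels[1L], "left"),
                 tolerance = 1e-6)
    expect_equal(r$right_cross,
                 oracle_crossing(g$z, g$v, r$half_levels[2L], "right"),
                 tolerance = 1e-6)
  }
})

test_that("all methods agree within one step on symmetric noise-free curves", {
  for (sigma in c(0.5, 1.5, 2.5)) {
    g <- gauss_curve(sigma = sigma, interval = 0.1 * sigma,
                     halfwidth = 5 * sigma)
    f <- vapply(fwhm_all(g), function(r) r$fwhm, numeric(1))
    expect_lt(max(f) - min(f), 0.1 * sigma)
  }
})

test_that("Gaussian fit is invariant to amplitude scaling and z translation", {
  g <- gauss_curve(sigma = 1.2, interval = 0.1, halfwidth = 5)
  base <- fwhm_gauss(g)$fwhm
  # invariance holds to optimizer precision, not machine precision
  g_scaled <- list(z = g$z, v = g$v * 0.37)
  expect_equal(fwhm_gauss(g_scaled)$fwhm, base, tolerance = 1e-5)
  g_shift <- list(z = g$z + 123.4, v = g$v)
  expect_equal(fwhm_gauss(g_shift)$fwhm, base, tolerance = 1e-5)
})

test_that("estimated FWHM increases strictly with true sigma (all methods)", {
  sigmas <- seq(0.6, 2.4, by = 0.3)
  ests <- sapply(sigmas, function(s) {
    g <- gauss_curve(sigma = s, interval = 0.05, halfwidth = 12)
    vapply(fwhm_all(g), function(r) r$fwhm, numeric(1))
  })
  for (m in rownames(ests)) expect_true(all(diff(ests[m, ]) > 0))
})

test_that("degenerate curves raise the documented errors", {
  # peak at the end of the range
  half <- list(z = 0:5, v = exp(-(0:5)^2 / 8))
  expect_error(fwhm_interp(half), class = "ctssp_truncated_profile")
  expect_error(fwhm_gauss(half), class = "ctssp_truncated_profile")
  # too few points
  expect_error(fwhm_interp(list(z = 1:4, v = c(0, 1, 0.5, 0))),
               class = "ctssp_input_error")
  # no crossing: curve never falls below the half level on the right
  flatr <- list(z = 1:7, v = c(0, 0.5, 1, 0.9, 0.8, 0.8, 0.8))
  expect_error(fwhm_interp(flatr, "left"), class = "ctssp_range_error")
})

test_that("under-resolved profiles trigger a warning", {
  g <- gauss_curve(sigma = 0.2, interval = 1, halfwidth = 5)
  expect_warning(fwhm_gauss(g), class = "ctssp_underresolved_warning")
})

test_that("Gaussian fit beats interpolation on precision under noise", {
  # 50 noisy replicates of a sigma = 1 curve; the fit pools all samples
  set.seed(314)
  true_fwhm <- ctssp:::GAUSS_FWHM_FACTOR
  est <- t(replicate(50, {
    g <- gauss_curve(sigma = 1, interval = 0.1)
    g$v <- g$v + rnorm(length(g$v), 0, 0.02)
    g$v <- g$v / max(g$v)
    c(gauss = fwhm_gauss(g)$fwhm, interp = fwhm_interp(g, "two_sided")$fwhm)
  }))
  expect_equal(mean(est[, "gauss"]), true_fwhm, tolerance = 0.02)
  expect_lt(sd(est[, "gauss"]), sd(est[, "interp"]))
})
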