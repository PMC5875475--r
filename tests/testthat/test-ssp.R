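test_that("sample_roi computes the ROI statistic per slice", {
  # slice 2 has one hot pixel of 100 in an otherwise zero image
  s <- make_flat_series(c(0, 0, 0), z = c(-1, 0, 1), hot = c(0, 100, 0))
  roi <- roi_spec("rectangle", center = c(4, 5), size = c(5, 5))
  mx <- sample_roi(s, roi, "max")
  mn <- sample_roi(s, roi, "mean")
  expect_equal(mx, c(0, 100, 0))
  expect_equal(mn, c(0, 100 / 25, 0))
  # uniform ROI: mean == max
  s2 <- make_flat_series(c(1, 7, 2), z = c(-1, 0, 1))
  expect_equal(sample_roi(s2, roi, "mean"), sample_roi(s2, roi, "max"))
})

test_that("ROI bounds and membership rules are enforced", {
  s <- make_flat_series(c(0, 1, 0), z = c(-1, 0, 1))
  expect_error(sample_roi(s, roi_spec("circle", c(2, 2), radius = 4), "max"),
               class = "ctssp_bounds_error")
  expect_error(sample_roi(s, roi_spec("rectangle", c(1, 1), size = c(8, 8)), "max"),
               class = "ctssp_bounds_error")
  # pixel-centre-within-radius, inclusive: radius 1 circle has 5 pixels
  mask <- ctssp:::roi_mask(roi_spec("circle", c(4, 4), radius = 1), c(8, 8))
  expect_identical(sum(mask), 5L)
})

test_that("background correction subtracts the outermost average", {
  # a 3-point toy profile is truncated by construction, hence the warning
  expect_warning(out <- background_correct(c(10, 50, 12)),
                 class = "ctssp_truncation_warning")
  expect_equal(as.numeric(out), c(-1, 39, 1))
  expect_equal(attr(out, "background"), 11)
  z <- background_correct(c(0, 0, 0, 0))
  expect_equal(as.numeric(z), rep(0, 4))
})

test_that("background correction warns when the tails are unresolved", {
  g <- gauss_curve(sigma = 1, interval = 0.2, halfwidth = 5)
  expect_silent(background_correct(100 + 500 * g$v))
  # truncated: range only +-1.2 sigma, profile far from baseline at ends
  gt <- gauss_curve(sigma = 1, interval = 0.2, halfwidth = 1.2)
  expect_warning(background_correct(100 + 500 * gt$v),
                 class = "ctssp_truncation_warning")
})

test_that("normalization scales the peak to exactly 1", {
  expect_equal(as.numeric(normalize(c(1, 2, 4))), c(0.25, 0.5, 1))
  expect_equal(as.numeric(normalize(c(5, 5))), c(1, 1))
  expect_equal(as.numeric(normalize(c(-1, 0, 2))), c(-0.5, 0, 1))
  expect_error(normalize(c(-3, -1)), class = "ctssp_degenerate_signal")
})

test_that("build_ssp composes the pipeline and errors on constant input", {
  cfg <- sim_config(true_fwhm = 0.98, thickness = 0.625, image_size = 16)
  s <- generate_series(cfg)
  roi <- auto_place_roi(s)
  ssp <- build_ssp(s, roi, "max")
  expect_equal(max(ssp$v), 1)
  expect_identical(ssp$z, s$z)
  # noise-free max-ROI curve equals the axial weight up to normalization
  # (background correction shifts the tails by the ~1e-12 edge weight)
  truth <- axial_weight(s$z, cfg)
  expect_equal(ssp$v, truth / max(truth), tolerance = 1e-9)
  # constant series: background correction zeroes everything -> degenerate
  flat <- make_flat_series(rep(7, 5), z = -2:2)
  expect_error(build_ssp(flat, roi_spec("circle", c(4, 4), radius = 2), "max"),
               class = "ctssp_degenerate_signal")
})

test_that("normalized SSP is invariant to positive rescaling of the pixels", {
  cfg <- sim_config(true_fwhm = 1.38, thickness = 1.25, image_size = 16)
  s <- generate_series(cfg)
  s_scaled <- s
  s_scaled$slices <- lapply(s$slices, function(sl) {
    sl$pixels <- sl$pixels * 3.7; sl
  })
  roi <- auto_place_roi(s)
  expect_equal(build_ssp(s_scaled, roi, "max")$v, build_ssp(s, roi, "max")$v,
               tolerance = 1e-12)
})

test_that("max-ROI SSP is invariant to ROI geometry containing the peak", {
  cfg <- sim_config(true_fwhm = 2.88, thickness = 2.5, image_size = 32)
  s <- generate_series(cfg)
  center <- auto_place_roi(s)$center
  ref <- NULL
  for (roi in roi_presets(center)) {
    v <- build_ssp(s, roi, "max")$v
    if (is.null(ref)) ref <- v else expect_equal(v, ref, tolerance = 1e-12)
  }
})

test_that("auto_place_roi finds the object and handles ambiguity", {
  # single hot pixel off-centre
  s <- make_flat_series(c(0, 0, 0), z = -1:1, hot = c(10, 100, 20),
                        hot_r = 3, hot_c = 6)
  roi <- auto_place_roi(s, radius = 2)
  expect_equal(roi$center, c(3, 6))
  # bead offset from image centre in a simulated series
  cfg <- sim_config(true_fwhm = 0.98, thickness = 0.625, image_size = 24,
                    object_xy = c(8, 17))
  roi2 <- auto_place_roi(generate_series(cfg))
  expect_equal(roi2$center, c(8, 17))
  # blank series: ambiguity warning, centred fallback
  blank <- make_flat_series(c(1, 1, 1), z = -1:1)
  expect_warning(roi3 <- auto_place_roi(blank, radius = 2),
                 class = "ctssp_ambiguity_warning")
  expect_equal(roi3$center, c(4.5, 4.5), tolerance = 1)
})

test_that("SSP curves export as (z, value) CSV", {
  cfg <- sim_config(true_fwhm = 0.98, thickness = 0.625, image_size = 8)
  s <- generate_series(cfg)
  ssp <- build_ssp(s, auto_place_roi(s), "max")
  f <- withr::local_tempfile(fileext = ".csv")
  write_ssp_csv(ssp, f)
  back <- read.csv(f)
  expect_identical(names(back), c("z", "value"))
  expect_equal(back$value, ssp$v, tolerance = 1e-12)
})
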