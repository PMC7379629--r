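test_that("fwhm recovers the width of rectangular, Gaussian and triangular profiles", {
  # rectangle of width w: FWHM within one sample spacing
  pos <- seq(-10, 10, by = 0.1)
  rect <- ifelse(abs(pos) <= 3, 2, 0)
  expect_lt(abs(fwhm(pos, rect) - 6), 0.1 + 1e-12)

  # Gaussian sigma = 3 mm at 0.1 mm sampling: 2*sqrt(2*ln 2)*3
  pos <- seq(-15, 15, by = 0.1)
  gauss <- exp(-pos^2 / (2 * 9))
  expect_equal(fwhm(pos, gauss), 2 * sqrt(2 * log(2)) * 3,
               tolerance = 0.005)

  # triangle peaking at 0, zero at +-w: half-max crossings at +-w/2
  w <- 8
  tri <- pmax(0, 1 - abs(pos) / w)
  expect_equal(fwhm(pos, tri), w, tolerance = 1e-9)
})

test_that("fwhm is scale invariant and rejects monotone profiles", {
  pos <- seq(-15, 15, by = 0.25)
  gauss <- 1.7 * exp(-pos^2 / 18)
  base <- fwhm(pos, gauss)
  for (lambda in c(0.01, 1, 3.7, 1e4)) {
    expect_equal(fwhm(pos, lambda * gauss), base, tolerance = 1e-12)
  }
  expect_error(fwhm(pos, exp(pos / 5)), "above both end values")
  expect_error(fwhm(seq(0, 10, 1), rep(c(1, 2), c(1, 10))), "above both")
})

test_that("equivalent_square matches sqrt(A*B), is symmetric, rejects non-positive", {
  expect_identical(equivalent_square(2, 2), 2)
  expect_equal(equivalent_square(0.5, 0.72), 0.6, tolerance = 1e-12)
  set.seed(11)
  A <- runif(50, 0.1, 12); B <- runif(50, 0.1, 12)
  expect_equal(equivalent_square(A, B), sqrt(A * B), tolerance = 1e-15)
  expect_equal(equivalent_square(A, B), equivalent_square(B, A))
  expect_equal(equivalent_square(A, A), A)
  expect_error(equivalent_square(0, 1), "positive")
  expect_error(equivalent_square(2, -1), "positive")
})

test_that("locate_field_center finds symmetric and translated field centers", {
  m0 <- make_gaussian_map(a = 2, b = 3, c = 3)
  expect_lt(max(abs(locate_field_center(m0))), 0.01)

  off <- c(1.3, -0.7)
  m1 <- make_gaussian_map(a = 2, b = 3, c = 3, offset = off)
  expect_lt(max(abs(locate_field_center(m1) - off)), 0.02)

  expect_error(locate_field_center(dose_map(matrix(1, 20, 20), 0.5)),
               "degenerate")
})

test_that("central_roi_dose averages correctly and checks bounds", {
  u <- dose_map(matrix(3.5, 30, 30), 0.2)
  roi <- central_roi_dose(u, c(0, 0), diameter = 0.5)
  expect_equal(roi$mean, 3.5)
  expect_equal(roi$sd, 0)

  g <- make_gaussian_map(a = 2, b = 3, c = 3, spacing = 0.1)
  roi <- central_roi_dose(g, c(0, 0), diameter = 0.5)
  # bounded between the edge-of-ROI dose and the peak
  expect_lte(roi$mean, 2)
  expect_gte(roi$mean, 2 * exp(-0.25^2 / (2 * 9)))

  expect_error(central_roi_dose(u, c(0, 0), diameter = 50), "outside")
})

test_that("central_roi_dose resamples when too few pixels fall in the ROI", {
  coarse <- make_gaussian_map(a = 2, b = 5, c = 5, spacing = 0.4)
  roi <- central_roi_dose(coarse, c(0, 0), diameter = 0.5)
  expect_gte(roi$n, 4)
  expect_lte(roi$mean, 2)
  expect_gt(roi$mean, 2 * exp(-0.25^2 / 50) * 0.999)
})

test_that("center finding plus fwhm reproduces construction widths across field sizes", {
  cfg <- noiseless_config()
  for (nom in c(0.5, 1, 2, 5, 10)) {
    m <- simulate_dose_map(nom, cfg, amplitude = 3)
    fs <- field_size_from_map(m)
    truth_mm <- analytic_field_fwhm(nom * 10, cfg$penumbra_sigma)
    expect_lt(abs(fs$A * 10 - truth_mm), cfg$spacing)
    expect_lt(abs(fs$B * 10 - truth_mm), cfg$spacing)
    expect_equal(fs$s_clin, sqrt(fs$A * fs$B), tolerance = 1e-9)
  }
})

test_that("dose maps survive a text round trip", {
  m <- make_gaussian_map(spacing = 0.5, half_extent_mm = 4)
  path <- tempfile(fileext = ".txt")
  write_dose_map_text(m, path)
  m2 <- read_dose_map_text(path)
  expect_equal(m2$spacing_x, m$spacing_x)
  expect_equal(m2$values, m$values, tolerance = 1e-6)
})
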