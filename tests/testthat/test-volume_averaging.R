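test_that("fit_central_gaussian recovers exact and noisy Gaussian parameters", {
  m <- make_gaussian_map(a = 2, b = 3, c = 4, spacing = 0.15)
  fit <- fit_central_gaussian(m, c(0, 0))
  expect_equal(fit$a, 2, tolerance = 1e-6)
  expect_equal(fit$b, 3, tolerance = 1e-6)
  expect_equal(fit$c, 4, tolerance = 1e-6)

  mn <- make_gaussian_map(a = 2, b = 3, c = 4, spacing = 0.15,
                          noise_sd = 0.005, seed = 42L)
  fitn <- fit_central_gaussian(mn, c(0, 0))
  expect_equal(fitn$a, 2, tolerance = 0.02)
  expect_equal(fitn$b, 3, tolerance = 0.02)
  expect_equal(fitn$c, 4, tolerance = 0.02)
})

test_that("fit_central_gaussian rejects uniform maps and flags flat centers", {
  expect_error(fit_central_gaussian(dose_map(matrix(2, 40, 40), 0.2),
                                    c(0, 0)),
               "uniform")
  # broad field: flat center, no volume averaging
  broad <- simulate_dose_map(10, noiseless_config(), amplitude = 5)
  fit <- fit_central_gaussian(broad, c(0, 0))
  expect_true(fit$flat)
  expect_identical(kvol_closed_form(1.95, fit), 1)
})

test_that("equivalent detector side follows pi*r^2 = d^2", {
  expect_equal(equivalent_detector_side(
    detector_geometry("W1", "circular", 0.5)), 0.8862, tolerance = 1e-4)
  expect_identical(equivalent_detector_side(
    detector_geometry("EDGE", "square", 0.8)), 0.8)
  expect_equal(equivalent_detector_side(
    detector_geometry("EBT3-ROI", "circular", 0.25)), 0.4431,
    tolerance = 1e-4)
  expect_error(detector_geometry("bad", "circular", -1), "positive")
})

test_that("closed-form kvol matches the quadrature oracle and its limits", {
  # frozen from the 2D Gauss-Legendre oracle
  expect_equal(kvol_closed_form(0.8862, b = 3, c = 3), 1.007288,
               tolerance = 1e-5)
  expect_equal(kvol_numeric(0.8862, b = 3, c = 3),
               kvol_closed_form(0.8862, b = 3, c = 3), tolerance = 1e-9)
  # small-footprint limit
  expect_lt(abs(kvol_closed_form(1e-4, b = 3, c = 3) - 1), 1e-8)
  # b/c symmetry
  expect_identical(kvol_closed_form(1.2, b = 2, c = 5),
                   kvol_closed_form(1.2, b = 5, c = 2))
  # very broad distribution
  expect_equal(kvol_numeric(1, b = 1e4, c = 1e4), 1, tolerance = 1e-7)
  expect_equal(kvol_numeric(1, b = 1, c = 1),
               kvol_closed_form(1, b = 1, c = 1), tolerance = 1e-9)
})

test_that("kvol is monotone in footprint size and in distribution width", {
  d_grid <- seq(0.2, 3, by = 0.2)
  k_d <- vapply(d_grid, kvol_closed_form, 0, b = 2.5, c = 3.5)
  expect_true(all(diff(k_d) > 0))
  b_grid <- seq(1, 10, by = 0.5)
  k_b <- vapply(b_grid, function(b) kvol_closed_form(1.5, b = b, c = 3), 0)
  expect_true(all(diff(k_b) < 0))
  expect_true(all(k_d >= 1) && all(k_b >= 1))
})

test_that("kvol ordering across detector footprints matches their sizes", {
  fit <- fit_central_gaussian(simulate_dose_map(0.5, noiseless_config(),
                                                amplitude = 3), c(0, 0))
  k <- vapply(c(0.4431, 0.8, 0.8862, 1.0635, 1.9501), kvol_closed_form, 0,
              fit = fit)
  expect_true(all(diff(k) > -1e-12))
  expect_lt(k[1], k[2])
  expect_lt(k[4], k[5])
})

test_that("no volume averaging remains at field sizes of 2 cm and above", {
  cfg <- noiseless_config()
  dets <- load_detector_table()
  for (nom in c(2, 3, 5)) {
    fit <- fit_central_gaussian(simulate_dose_map(nom, cfg, amplitude = 3),
                                c(0, 0))
    tab <- kvol_table(fit, dets)
    expect_true(all(round(tab$k_vol, 3) == 1.000),
                label = sprintf("kvol rounds to 1.000 at %g cm", nom))
  }
})
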