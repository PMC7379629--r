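test_that("correct_film_reading multiplies signal by its kvol", {
  expect_equal(correct_film_reading(0.455, 1.002), 0.45591)
  expect_identical(correct_film_reading(0.7, 1), 0.7)
  set.seed(2)
  s <- runif(20, 0.1, 2); k <- 1 + runif(20, 0, 0.05)
  expect_equal(correct_film_reading(s, k) / s, k, tolerance = 1e-15)
  expect_error(correct_film_reading(-1, 1), "positive")
})

test_that("sauer_wilbert has the expected asymptote and half-saturation", {
  p <- sw_params(0.8, 2.5, 0.5, 0.3, 0.12)
  expect_equal(sauer_wilbert(1e6, p), 0.8 + 0.3, tolerance = 1e-6)
  p0 <- sw_params(0.8, 2.5, 0.5, 0, 0.12)
  expect_equal(sauer_wilbert(0.5, p0), 0.4, tolerance = 1e-12)
  # published parameter set evaluates near unity at the reference size
  elekta <- beam_params("Elekta 6 MV WFF")
  direct <- 0.751 * 10^2.701 / (0.542^2.701 + 10^2.701) +
    0.384 * (1 - exp(-0.105 * 10))
  expect_equal(sauer_wilbert(10, elekta), direct, tolerance = 1e-12)
  expect_error(sauer_wilbert(-1, p), "positive")
})

test_that("normalized curve equals 1 at 10 cm for any parameters", {
  set.seed(9)
  for (i in 1:20) {
    p <- sw_params(runif(1, 0.3, 1.2), runif(1, 1, 4), runif(1, 0.2, 1),
                   runif(1, -0.5, 2), runif(1, 0.01, 0.5))
    expect_identical(evaluate_output_factor(p, 10), 1)
  }
  expect_error(evaluate_output_factor(beam_params(1), 25), "in \\(0, 20\\]")
})

test_that("published parameter sets reproduce printed discrete output factors", {
  # spot checks at measured field sizes
  expect_equal(evaluate_output_factor(beam_params("Elekta 6 MV WFF"), 1.03),
               0.678, tolerance = 0.003)
  expect_equal(evaluate_output_factor(beam_params("Varian 10 MV FFF"), 1.99),
               0.828, tolerance = 0.003)
})

test_that("output factors increase monotonically for all published parameter sets", {
  S <- seq(0.5, 10, by = 0.05)
  for (bm in beam_catalog()$beam) {
    om <- evaluate_output_factor(beam_params(bm), S)
    expect_true(all(diff(om) > 0), label = paste("monotone:", bm))
  }
})

test_that("fit_output_factor_curve recovers a known curve from clean and noisy points", {
  truth <- beam_params("Elekta 10 MV FFF")
  sc <- sclin_catalog()
  s <- sc$s_clin[sc$beam == "Elekta 10 MV FFF"]
  y <- sauer_wilbert(s, truth) / sauer_wilbert(10, truth)
  pts <- data.frame(s_clin = s, value = y, sd = 0)
  fit <- fit_output_factor_curve(pts, seed = 1L, n_boot = 0)
  Sg <- seq(0.5, 10, by = 0.5)
  rel <- evaluate_output_factor(fit, Sg) / evaluate_output_factor(truth, Sg) - 1
  expect_lt(max(abs(rel)), 0.001)

  set.seed(17)
  ptsn <- data.frame(s_clin = s, value = y * (1 + rnorm(9, sd = 0.01)),
                     sd = 0.01 * y)
  fitn <- fit_output_factor_curve(ptsn, seed = 2L, n_boot = 0)
  Sg <- Sg[Sg >= 0.8]
  reln <- evaluate_output_factor(fitn, Sg) / evaluate_output_factor(truth, Sg) - 1
  expect_lt(max(abs(reln)), 0.01)
})

test_that("fit_output_factor_curve demands field-size coverage", {
  expect_error(fit_output_factor_curve(
    data.frame(s_clin = 2, value = 0.8, sd = 0.01)), "coverage")
  expect_error(fit_output_factor_curve(
    data.frame(s_clin = c(2, 3, 4, 5, 6, 10), value = runif(6, 0.8, 1),
               sd = 0.01)), "coverage")
})

test_that("tabulated output factors carry growing uncertainty toward small fields", {
  truth <- beam_params("Elekta 6 MV WFF")
  sc <- sclin_catalog()
  s <- sc$s_clin[sc$beam == "Elekta 6 MV WFF"]
  y <- sauer_wilbert(s, truth) / sauer_wilbert(10, truth)
  set.seed(23)
  pts <- data.frame(s_clin = s, value = y * (1 + rnorm(9, sd = 0.008)),
                    sd = 0.008 * y)
  fit <- fit_output_factor_curve(pts, seed = 3L, n_boot = 150)
  tab <- tabulate_output_factors(fit, c(0.5, 5, 10))
  expect_equal(tab$omega[tab$s_clin == 10], 1)
  expect_equal(tab$sd[tab$s_clin == 10], 0, tolerance = 1e-12)
  # relative fit uncertainty is largest at the smallest field
  rel <- tab$sd / tab$omega
  expect_gt(rel[tab$s_clin == 0.5], rel[tab$s_clin == 5])
})
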