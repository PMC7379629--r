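# Fixtures built in code: analytic maps with known truth and memoized
# synthetic campaigns shared across test files.

# Noiseless bivariate-Gaussian dose map with known (a, b, c).
make_gaussian_map <- function(a = 2, b = 3, c = 4, spacing = 0.2,
                              half_extent_mm = 12, noise_sd = 0,
                              seed = 1L, offset = c(0, 0)) {
  u <- seq(-half_extent_mm, half_extent_mm, by = spacing)
  gx <- exp(-0.5 * ((u - offset[1]) / b)^2)
  gy <- exp(-0.5 * ((u - offset[2]) / c)^2)
  vals <- a * outer(gy, gx)
  if (noise_sd > 0) {
    set.seed(seed)
    vals <- vals * (1 + stats::rnorm(length(vals), sd = noise_sd))
    vals[vals < 0] <- 0
  }
  dose_map(vals, spacing, spacing)
}

noiseless_config <- function(beam = "Elekta 6 MV WFF", seed = 5L, ...) {
  sim_config(beam = beam, seed = seed, film_piece_sd = 0, film_pixel_sd = 0,
             w1_sd = 0, diode_sd = 0, ...)
}

# Memoize the expensive shared objects.
.fixture_env <- new.env(parent = emptyenv())

noiseless_campaign <- function() {
  if (is.null(.fixture_env$camp))
    .fixture_env$camp <- simulate_campaign(noiseless_config())
  .fixture_env$camp
}

noiseless_pipeline <- function() {
  if (is.null(.fixture_env$res))
    .fixture_env$res <- run_full_pipeline(noiseless_campaign(), n_boot = 0)
  .fixture_env$res
}

# Independent FWHM oracle for the erf-core profile model, re-coded here
# (bisection, no package internals).
oracle_model_fwhm <- function(w_mm, sigma_mm) {
  g <- function(u) 0.5 * (pracma::erf((w_mm / 2 - u) / (sigma_mm * sqrt(2))) +
                            pracma::erf((w_mm / 2 + u) / (sigma_mm * sqrt(2))))
  half <- g(0) / 2
  lo <- 0; hi <- w_mm / 2 + 10 * sigma_mm
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > half) lo <- mid else hi <- mid
  }
  lo + hi
}
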