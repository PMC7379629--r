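test_that("broad simulated fields are flat at the center, small ones are not", {
  cfg <- noiseless_config()
  broad <- simulate_dose_map(10, cfg, amplitude = 5)
  center <- interp_dose(broad, 0, 0)
  edge <- interp_dose(broad, c(1.5, -1.5, 0, 0), c(0, 0, 1.5, -1.5))
  expect_lt(max(abs(edge / center - 1)), 0.001)
  small <- simulate_dose_map(0.5, cfg, amplitude = 5)
  expect_lt(interp_dose(small, 1.5, 0) / interp_dose(small, 0, 0), 0.95)
})

test_that("simulated FWHM matches the independent root-finding oracle", {
  cfg <- noiseless_config()
  for (nom in c(0.5, 0.8, 2)) {
    m <- simulate_dose_map(nom, cfg, amplitude = 3)
    fs <- field_size_from_map(m)
    expect_lt(abs(fs$A * 10 - oracle_model_fwhm(nom * 10,
                                                cfg$penumbra_sigma)), 0.2)
  }
})

test_that("same seed reproduces maps and campaigns bit-identically", {
  cfg <- sim_config(seed = 31L)
  m1 <- simulate_dose_map(1, cfg, seed = 7L)
  m2 <- simulate_dose_map(1, cfg, seed = 7L)
  expect_identical(m1, m2)
  c1 <- simulate_campaign(sim_config(seed = 13L, n_film = 1L))
  c2 <- simulate_campaign(sim_config(seed = 13L, n_film = 1L))
  expect_identical(c1, c2)
})

test_that("noiseless readings reproduce the planted ratios exactly", {
  ident <- list("probe" = list(a = 1, b = 1, c = 0, d = 0))
  cfg <- noiseless_config(detector_perturbations = ident)
  r <- simulate_readings(cfg, "probe")
  ft <- r[r$session == "clin", ]
  m_by_field <- tapply(ft$m, ft$nominal, mean)
  m_ref <- mean(r$m[r$session != "clin"])
  camp_truth <- simulate_campaign(cfg)$truth
  expect_equal(as.numeric(m_by_field[as.character(c(0.5, 1, 5, 10))] / m_ref),
               as.numeric(camp_truth$omega[as.character(c(0.5, 1, 5, 10))]),
               tolerance = 1e-12)
})

test_that("reference-field readings are emitted for both bracketing sessions", {
  camp <- noiseless_campaign()
  det <- camp$detector_readings
  for (dn in unique(det$detector)) {
    d <- det[det$detector == dn, ]
    expect_equal(sum(d$session == "ref_pre"), camp$config$n_repeats)
    expect_equal(sum(d$session == "ref_post"), camp$config$n_repeats)
    expect_true(all(d$nominal[d$session != "clin"] == 10))
  }
})

test_that("repeat noise produces sample SDs at the configured level", {
  # per-field SD of the mean of 3 repeats ~ 1%/sqrt(3) on average,
  # allowing for the small-sample bias of the sample SD (c4 ~ 0.886)
  rels <- c()
  for (s in 1:100) {
    cfg <- sim_config(seed = 2000L + s, diode_sd = 0.01)
    r <- simulate_readings(cfg, "IBA SFD diode",
                           seed = s)
    clin <- r[r$session == "clin", ]
    per <- tapply(seq_len(nrow(clin)), clin$nominal, function(i)
      sd(clin$m[i]) / sqrt(3) / mean(clin$m[i]))
    rels <- c(rels, per)
  }
  expect_equal(mean(rels), 0.886 * 0.01 / sqrt(3), tolerance = 0.05)
})

test_that("config validation rejects missing seeds and bad noise", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, penumbra_sigma = -1))
  expect_error(simulate_readings(sim_config(seed = 1), "no such detector"),
               "unknown detector")
})
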