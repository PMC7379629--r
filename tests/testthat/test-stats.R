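test_that("summary t-test gives p = 0.5 for identical groups (one-tailed)", {
  for (n in c(2, 3, 10)) {
    tt <- t_test_from_summary(0.7, 0.01, n, 0.7, 0.01, n, tails = 1L)
    expect_equal(tt$p, 0.5)
    expect_equal(tt$t, 0)
  }
  expect_error(t_test_from_summary(1, 0, 3, 1, 0, 3), "undefined")
  expect_error(t_test_from_summary(1, 0.1, 1, 1.1, 0.1, 3), "n >= 2")
})

test_that("welch and pooled agree in the balanced equal-variance case", {
  a <- t_test_from_summary(0.454, 0.005, 3, 0.478, 0.005, 3,
                           variance_mode = "welch")
  b <- t_test_from_summary(0.454, 0.005, 3, 0.478, 0.005, 3,
                           variance_mode = "pooled")
  expect_equal(a$t, b$t, tolerance = 1e-12)
  expect_equal(a$df, b$df, tolerance = 1e-9)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("t is antisymmetric and one-tailed p halves the matching two-tailed p", {
  x <- t_test_from_summary(0.454, 0.005, 3, 0.478, 0.006, 3, tails = 2L)
  y <- t_test_from_summary(0.478, 0.006, 3, 0.454, 0.005, 3, tails = 2L)
  expect_equal(x$t, -y$t, tolerance = 1e-12)
  one <- t_test_from_summary(0.454, 0.005, 3, 0.478, 0.006, 3, tails = 1L)
  expect_equal(one$p, x$p / 2, tolerance = 1e-12)
})

test_that("summary t-test agrees with stats::t.test on reconstructed raw data", {
  # triplets with exact mean m and sd s: m + s * c(-1, 0, 1)
  make3 <- function(m, s) m + s * c(-1, 0, 1)
  cases <- list(c(0.454, 0.005, 0.478, 0.006),
                c(0.92, 0.012, 0.95, 0.009),
                c(1.001, 0.002, 0.999, 0.001))
  for (cs in cases) {
    x <- make3(cs[1], cs[2]); y <- make3(cs[3], cs[4])
    ours_w <- t_test_from_summary(mean(x), sd(x), 3, mean(y), sd(y), 3,
                                  tails = 2L, variance_mode = "welch")
    ref_w <- stats::t.test(y, x, var.equal = FALSE)
    expect_equal(ours_w$p, ref_w$p.value, tolerance = 1e-10)
    expect_equal(ours_w$df, unname(ref_w$parameter), tolerance = 1e-8)
    ours_p <- t_test_from_summary(mean(x), sd(x), 3, mean(y), sd(y), 3,
                                  tails = 2L, variance_mode = "pooled")
    ref_p <- stats::t.test(y, x, var.equal = TRUE)
    expect_equal(ours_p$p, ref_p$p.value, tolerance = 1e-10)
  }
})

test_that("combine_relative_sd is the root sum of squares", {
  expect_equal(combine_relative_sd(c(0.003, 0.004)), 0.005)
  expect_equal(combine_relative_sd(0.017), 0.017)
  set.seed(6)
  x <- runif(12, 0, 0.05)
  expect_equal(combine_relative_sd(x), sqrt(sum(x^2)), tolerance = 1e-15)
  m <- matrix(runif(10, 0, 0.02), ncol = 2)
  expect_equal(combine_relative_sd(m), sqrt(rowSums(m^2)), tolerance = 1e-15)
  expect_error(combine_relative_sd(c(0.1, -0.1)), ">= 0")
})

test_that("compare_tables runs field-matched tests", {
  a <- data.frame(nominal = c(0.5, 1, 10), omega = c(0.454, 0.678, 1.001),
                  sd = c(0.005, 0.005, 0.001))
  b <- data.frame(nominal = c(0.5, 1, 10), omega = c(0.478, 0.703, 0.999),
                  sd = c(0.006, 0.006, 0.001))
  res <- compare_tables(a, b, n = 3L, tails = 1L)
  expect_equal(nrow(res), 3)
  expect_true(all(res$p >= 0 & res$p <= 1))
  # larger FFF-like values drive a positive t in the directional test
  expect_true(all(res$t[res$nominal < 10] > 0))
})
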