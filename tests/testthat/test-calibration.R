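test_that("the saturating forward model has the right shape and limits", {
  expect_equal(saturation_absorbance(0), 0)
  expect_lt(abs(saturation_absorbance(25 / 0.0022) - 3.29), 1e-9)
  # direct evaluation at c = 1000 with the default constants
  expect_equal(saturation_absorbance(1000), 3.29 * (1 - exp(-2.2)))
  expect_equal(saturation_absorbance(1000), 2.9255, tolerance = 1e-4)

  cc <- seq(0, 3000, 10)
  a <- saturation_absorbance(cc)
  expect_true(all(diff(a) > 0))          # strictly increasing
  expect_true(all(diff(diff(a)) < 0))    # concave
  expect_true(all(a < 3.29))
  # initial slope is A_max * k
  h <- 1e-6
  expect_equal(saturation_absorbance(h) / h, 3.29 * 0.0022,
               tolerance = 1e-6)
  expect_error(saturation_absorbance(-1), "non-negative")
})

test_that("the biomass estimator inverts the forward model exactly", {
  expect_equal(estimate_biomass_od440(0), 0)
  od100 <- saturation_absorbance(100)
  expect_equal(od100, 0.6497, tolerance = 1e-4)
  expect_equal(estimate_biomass_od440(od100), 100, tolerance = 1e-9)
  expect_error(estimate_biomass_od440(3.29), "dilute the sample")
  expect_error(estimate_biomass_od440(3.5), "dilute the sample")
  expect_error(estimate_biomass_od440(-0.1), "non-negative")
})

test_that("fit_linear wraps OLS with model methods", {
  x <- 1:6
  m <- fit_linear(x, 0.3 * x + 0.1)
  expect_equal(m$r2, 1)
  expect_equal(unname(coef(m)), c(0.1, 0.3))
  expect_equal(predict(m, 10), 3.1)
  expect_equal(estimate_biomass(m, 3.1), 10)
  expect_equal(unname(residuals(m)), rep(0, 6))
  expect_error(fit_linear(1:2, 1:2), "at least 3")
})

test_that("fit_box_lucas recovers known parameters from noiseless data", {
  x <- 1080 * paper_ratios
  m <- fit_box_lucas(x, saturation_absorbance(x))
  expect_equal(coef(m)[["A_max"]], 3.29, tolerance = 1e-6)
  expect_equal(coef(m)[["k"]], 0.0022, tolerance = 1e-6)
  expect_equal(m$r2, 1, tolerance = 1e-12)
  expect_true(m$converged)
  # forward-inverse composition through the fitted model
  expect_equal(estimate_biomass(m, predict(m, 500)), 500,
               tolerance = 1e-6)
  expect_error(fit_box_lucas(x, rep(0, 10)), "degenerate")
})

test_that("fit_box_lucas degrades gracefully to the linear regime", {
  # max(b * x) = 0.01: only the product a*b is well identified, and it
  # must match the dilute-regime Beer-Lambert slope
  x <- seq(0.1, 1, length.out = 10) * (0.01 / 0.0022)
  y <- saturation_absorbance(x)
  p <- coef(fit_box_lucas(x, y))
  slope <- coef(fit_linear(x, y))[["slope"]]
  expect_equal(p[["A_max"]] * p[["k"]], slope, tolerance = 0.01)
})

test_that("fit_box_lucas agrees with an independent Levenberg-Marquardt fit", {
  skip_if_not_installed("minpack.lm")
  set.seed(21)
  x <- 1080 * paper_ratios
  y <- saturation_absorbance(x) * (1 + rnorm(10, 0, 0.01))
  ours <- coef(fit_box_lucas(x, y))
  lmref <- minpack.lm::nlsLM(y ~ a * (1 - exp(-b * x)),
                             start = list(a = 3, b = 0.002))
  expect_equal(ours[["A_max"]], coef(lmref)[["a"]], tolerance = 1e-6)
  expect_equal(ours[["k"]], coef(lmref)[["b"]], tolerance = 1e-6)
})

test_that("deep-saturation data prefer the saturating family", {
  x <- 1080 * paper_ratios
  y <- saturation_absorbance(x)
  cmp <- compare_models(x, y)
  expect_lt(cmp$linear$r2, cmp$saturating$r2)
  expect_equal(cmp$preferred, "saturating")
})

test_that("exactly linear data resolve the family tie to linear", {
  x <- 1080 * paper_ratios
  cmp <- compare_models(x, 0.001 * x)
  expect_lt(abs(cmp$saturating$r2 - cmp$linear$r2), 1e-9)
  expect_equal(cmp$preferred, "linear")
  # nested-truth invariant: the saturating family can always do at least
  # as well as the line it contains in the small-argument limit
  expect_gte(cmp$saturating$r2, cmp$linear$r2 - 1e-9)
})

test_that("a minimal three-point comparison still produces a report", {
  x <- c(10, 500, 2000)
  cmp <- compare_models(x, saturation_absorbance(x))
  expect_s3_class(cmp$linear, "calib_model")
  expect_s3_class(cmp$saturating, "calib_model")
  expect_output(print(cmp), "preferred")
})

test_that("noisy parameter recovery is accurate in the median", {
  set.seed(31)
  x <- 1080 * paper_ratios
  err <- t(replicate(50, {
    y <- saturation_absorbance(x) * (1 + rnorm(10, 0, 0.01))
    p <- coef(fit_box_lucas(x, y))
    c(abs(p[["A_max"]] - 3.29) / 3.29, abs(p[["k"]] - 0.0022) / 0.0022)
  }))
  expect_lt(median(err[, 1]), 0.05)
  expect_lt(median(err[, 2]), 0.05)
})

test_that("calibration model methods print and summarize coherently", {
  x <- 1080 * paper_ratios
  m <- fit_box_lucas(x, saturation_absorbance(x), wavelength = 440)
  expect_output(print(m), "saturating calibration model")
  expect_output(print(m), "440 nm")
  expect_output(print(summary(m)), "Residual standard error")
  expect_equal(fitted(m), predict(m))
})
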