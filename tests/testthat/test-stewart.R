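test_that("an exact line is recovered to machine precision", {
  std <- data.frame(conc_mg_ml = c(0.005, 0.02, 0.035, 0.05),
                    absorbance = 2 * c(0.005, 0.02, 0.035, 0.05) + 0.1)
  cal <- fit_calibration(std)
  expect_equal(cal$slope, 2, tolerance = 1e-12)
  expect_equal(cal$intercept, 0.1, tolerance = 1e-12)
  expect_equal(cal$valid_range, c(0.005, 0.05))
})

test_that("weighted estimates match a hand-rolled normal-equations oracle", {
  std <- simulate_stewart_standards(noise_sd = 0.01, seed = 8)
  std$se <- std$se + 0.002  # make weights clearly heteroscedastic
  cal <- fit_calibration(std)
  # weighted normal equations, assembled independently
  w <- 1 / std$se^2
  X <- cbind(1, std$conc_mg_ml)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * std$absorbance))
  expect_equal(cal$intercept, beta[1, 1], tolerance = 1e-10)
  expect_equal(cal$slope, beta[2, 1], tolerance = 1e-10)
  expect_true(cal$weighted)
})

test_that("equal weights reduce to ordinary least squares", {
  std <- simulate_stewart_standards(noise_sd = 0.01, seed = 9)
  std$se <- rep(0.004, nrow(std))
  cal_w <- fit_calibration(std)
  std$se <- NULL
  cal_u <- fit_calibration(std)
  expect_false(cal_u$weighted)
  expect_equal(cal_w$slope, cal_u$slope, tolerance = 1e-10)
  expect_equal(cal_w$intercept, cal_u$intercept, tolerance = 1e-10)
})

test_that("degenerate designs are rejected", {
  expect_error(fit_calibration(data.frame(conc_mg_ml = c(0.01, 0.02),
                                          absorbance = c(0.2, 0.4))),
               "3")
  expect_error(fit_calibration(data.frame(conc_mg_ml = rep(0.01, 4),
                                          absorbance = 1:4 / 10)),
               "degenerate")
  expect_error(fit_calibration(data.frame(conc_mg_ml = c(-0.01, 0.02, 0.03),
                                          absorbance = c(1, 2, 3) / 10)),
               "positive")
})

test_that("inverse prediction round-trips and flags extrapolation", {
  cal <- fit_calibration(simulate_stewart_standards(noise_sd = 0.005,
                                                    seed = 10))
  # A = slope*c + intercept with zero SEs recovers c * dilution exactly
  p <- predict_concentration(cal, cal$slope * 0.03 + cal$intercept,
                             abs_se = 0, dilution = 41)
  expect_equal(p$conc, 0.03 * 41, tolerance = 1e-12)
  expect_false(p$extrapolated)
  # A = intercept maps to zero concentration (and flags extrapolation)
  expect_warning(p0 <- predict_concentration(cal, cal$intercept), "outside")
  expect_equal(p0$conc, 0)
  expect_true(p0$extrapolated)
  # linear in absorbance and dilution
  p1 <- predict_concentration(cal, cal$intercept + 0.4, dilution = 1)
  p2 <- predict_concentration(cal, cal$intercept + 0.8, dilution = 1)
  expect_equal(p2$conc, 2 * p1$conc, tolerance = 1e-12)
  p3 <- predict_concentration(cal, cal$intercept + 0.4, dilution = 3)
  expect_equal(p3$conc, 3 * p1$conc, tolerance = 1e-12)
})

test_that("every calibration standard round-trips within 2 propagated SEs", {
  std <- simulate_stewart_standards(noise_sd = 0.01, seed = 12)
  cal <- fit_calibration(std)
  truth <- 20 * std$conc_mg_ml + 0.05
  for (i in seq_len(nrow(std))) {
    p <- suppressWarnings(
      predict_concentration(cal, std$absorbance[i], std$se[i]))
    expect_lt(abs(p$conc - std$conc_mg_ml[i]),
              2 * p$se + 2 * std$se[i] / cal$slope)
  }
})

test_that("prediction SE agrees with a 100,000-draw Monte Carlo", {
  cal <- fit_calibration(simulate_stewart_standards(noise_sd = 0.01,
                                                    seed = 5))
  a_obs <- cal$slope * 0.02 + cal$intercept
  p <- predict_concentration(cal, a_obs, abs_se = 0.005, dilution = 41)
  set.seed(7)
  # joint draws of (intercept, slope) from the fit covariance plus the
  # absorbance error, pushed through the inverse prediction
  L <- chol(cal$vcov)
  ab <- matrix(rnorm(2e5), ncol = 2) %*% L
  a_draw <- rnorm(1e5, a_obs, 0.005)
  c_draw <- 41 * (a_draw - (cal$intercept + ab[, 1])) /
    (cal$slope + ab[, 2])
  expect_equal(p$se, sd(c_draw), tolerance = 0.05)
})

test_that("forced-origin calibration fixes the intercept at zero", {
  std <- simulate_stewart_standards(true_intercept = 0, noise_sd = 0.005,
                                    seed = 13)
  cal <- fit_calibration(std, through_origin = TRUE)
  expect_identical(cal$intercept, 0)
  expect_equal(cal$slope, 20, tolerance = 0.05)
})
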