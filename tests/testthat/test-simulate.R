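test_that("generators are bit-identical under a fixed seed", {
  d <- size_distribution(c(0.002, 0.004), c(0.3, 0.7))
  expect_identical(simulate_correlogram(d, seed = 3),
                   simulate_correlogram(d, seed = 3))
  expect_identical(simulate_emission_spectrum(50, seed = 3),
                   simulate_emission_spectrum(50, seed = 3))
  expect_identical(simulate_stewart_standards(seed = 3),
                   simulate_stewart_standards(seed = 3))
  s1 <- simulate_extrusion_experiment(seed = 3)
  s2 <- simulate_extrusion_experiment(seed = 3)
  expect_identical(s1$pair, s2$pair)
  # and different seeds differ
  expect_false(identical(simulate_correlogram(d, seed = 3),
                         simulate_correlogram(d, seed = 4)))
})

test_that("a noiseless monodisperse correlogram is the closed-form exponential", {
  g0 <- 0.0024
  cor <- simulate_correlogram(size_distribution(g0, 1), B = 1, beta = 0.8,
                              noise_sd = 0)
  expect_equal(cor$g2, 1 + 0.8 * exp(-2 * g0 * cor$lag_us),
               tolerance = 1e-12)
})

test_that("generated extrusion pairs satisfy closure by construction", {
  for (rf in c(0.05, 0.15, 0.4)) {
    sim <- simulate_extrusion_experiment(residual_fraction = rf, seed = 60)
    tr <- sim$truth
    expect_equal(tr$c1 * 0.8 + tr$c2 * 1.0, 1, tolerance = 1e-12)
    expect_equal(tr$c2 / tr$c1, rf / (1 - rf) * 0.8, tolerance = 1e-12)
  }
})

test_that("noise-free experiments invert to the exact truth", {
  sim <- simulate_extrusion_experiment(cv = 0, n_rep = 1, seed = 61)
  res <- suppressWarnings(solve_concentrations(sim$pair))
  expect_equal(res$c1, sim$truth$c1, tolerance = 1e-12)
  expect_equal(res$c2, sim$truth$c2, tolerance = 1e-12)
})

test_that("a vanishing residual fraction leaves extrusion II at the noise floor", {
  expect_error(simulate_extrusion_experiment(residual_fraction = 1),
               "residual_fraction")
  # residual_fraction = 0 gives I2 = noise only; the pair constructor
  # refuses non-positive intensities, or the solver flags the case
  got_flag <- tryCatch({
    sim <- simulate_extrusion_experiment(residual_fraction = 0, seed = 62)
    res <- solve_concentrations(sim$pair)
    "i2_below_noise" %in% res$flags
  }, error = function(e) grepl("positive", conditionMessage(e)))
  expect_true(got_flag)
})

test_that("coverage of 2-SE intervals matches the small-sample oracle over 500 runs", {
  # with triplicate-based SEs (2 df per intensity) the error/SE pivot is
  # t-like with about 4 effective df, whose 2-SE two-sided coverage is
  # 88.6% +- 0.2% (20,000-replicate oracle), not the Gaussian 95%
  hits <- logical(500)
  for (i in 1:500) {
    sim <- simulate_extrusion_experiment(cv = 0.02, seed = i)
    res <- solve_concentrations(sim$pair)
    hits[i] <- abs(res$c1 - sim$truth$c1) <= 2 * res$se_c1
  }
  expect_gte(mean(hits), 0.85)
  expect_lte(mean(hits), 0.92)
})

test_that("recovery holds across the size / residual-fraction sweep", {
  cfg <- optical_config()
  for (d_nm in c(50, 100, 200)) {
    for (rf in c(0.05, 0.2, 0.4)) {
      dist <- size_distribution(gamma_from_diameter(d_nm, cfg), 1)
      sim <- simulate_extrusion_experiment(residual_fraction = rf,
                                           dist = dist, cv = 0.02,
                                           seed = round(d_nm * 100 + rf * 10))
      res <- solve_concentrations(sim$pair)
      expect_equal(res$c1, sim$truth$c1, tolerance = 0.1)
      expect_equal(res$c2, sim$truth$c2, tolerance = 0.2)
    }
  }
})

test_that("simulated emission spectra hit their target area", {
  sp <- simulate_emission_spectrum(100, noise_sd = 0, baseline = 0)
  expect_equal(integrate_elastic_peak(sp, window_nm = 6), 100,
               tolerance = 0.005)
  sp0 <- simulate_emission_spectrum(0, noise_sd = 0)
  expect_equal(integrate_elastic_peak(sp0, window_nm = 6), 0,
               tolerance = 1e-8)
})

test_that("Stewart generator respects the assay's standard range and truth", {
  std <- simulate_stewart_standards(seed = 70)
  expect_equal(min(std$conc_mg_ml), 0.005)
  expect_equal(max(std$conc_mg_ml), 0.050)
  # noiseless generation recovers the line exactly
  std0 <- simulate_stewart_standards(noise_sd = 0, seed = 71)
  cal <- fit_calibration(std0)
  expect_equal(cal$slope, 20, tolerance = 1e-9)
  expect_equal(cal$intercept, 0.05, tolerance = 1e-9)
  # Monte-Carlo slope distribution centred on the truth
  sl <- vapply(1:200, function(s)
    fit_calibration(simulate_stewart_standards(noise_sd = 0.01, n_rep = 3,
                                               seed = 700 + s))$slope, 0)
  expect_lt(abs(mean(sl) - 20) / 20, 0.01)
})
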