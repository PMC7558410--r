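test_that("extrusion pair validates bookkeeping and summarizes replicates", {
  expect_error(extrusion_pair(1, 0.8, 0.7, 50, 5, 200, 250), "exceed")
  expect_error(extrusion_pair(1, 0.8, 1.8, 0.5, 5, 200, 250), ">= 1")
  expect_error(extrusion_pair(1, 0.8, 1.8, 50, 5, 200, 250, v2 = 1.5),
               "dead volume")
  p <- extrusion_pair(1, 0.8, 1.8, 50, 5, c(199, 200, 201),
                      c(248, 250, 252))
  expect_equal(p$i1, 200)
  expect_equal(p$se_i1, sd(c(199, 200, 201)) / sqrt(3))
  # buffer subtraction with quadrature SEs
  pb <- extrusion_pair(1, 0.8, 1.8, 50, 5, 210, 260, se_i1 = 3, se_i2 = 4,
                       buffer = 10, se_buffer = 1)
  expect_equal(pb$i1, 200)
  expect_equal(pb$se_i1, sqrt(3^2 + 1))
  expect_equal(pb$se_i2, sqrt(4^2 + 1))
})

test_that("gamma is the dilution-corrected intensity ratio, setup-independent", {
  expect_identical(compute_gamma(200, 50, 250, 5), 8)
  expect_identical(compute_gamma(100, 3, 100, 3), 1)
  expect_identical(compute_gamma(3.7 * 200, 50, 3.7 * 250, 5), 8)
  expect_error(compute_gamma(200, 50, -1, 5), "extrusion-II")
})

test_that("the mass-closure solution matches the hand-evaluated reference", {
  res <- solve_concentrations(reference_pair())
  expect_equal(res$alpha, 1.25)
  expect_equal(res$upsilon, 1.25)
  expect_equal(res$gamma, 8)
  expect_equal(res$c2, 1.25 / 9.25, tolerance = 1e-12)  # 0.13514
  expect_equal(res$c1, 1.25 * 8 / 9.25, tolerance = 1e-12)  # 1.08108
  # closure: 1.0811*0.8 + 0.1351*1.0 = 1.000
  expect_equal(res$c1 * 0.8 + res$c2 * 1.0, 1, tolerance = 1e-12)
  expect_equal(unname(coef(res)), c(res$c1, res$c2))
})

test_that("closure and ratio invariants hold for 10,000 randomized pairs", {
  set.seed(20)
  worst_closure <- worst_ratio <- 0
  for (i in 1:10000) {
    p <- random_valid_pair()
    r <- solve_concentrations(p)
    worst_closure <- max(worst_closure, abs(
      (r$c1 * p$v1 + r$c2 * (p$vt - p$v1) - p$m0) / p$m0))
    worst_ratio <- max(worst_ratio, abs(r$c1 / r$c2 / r$gamma - 1))
    if (i <= 100) {
      # monotone structure: C2 decreases and C1 increases with gamma
      expect_gt(r$c1, 0); expect_gt(r$c2, 0)
    }
  }
  expect_lt(worst_closure, 1e-12)
  expect_lt(worst_ratio, 1e-12)
})

test_that("C1 rises and C2 falls monotonically with gamma at fixed bookkeeping", {
  gammas <- c(0.5, 1, 2, 5, 10, 50, 1000)
  res <- lapply(gammas, function(g)
    solve_concentrations(extrusion_pair(1, 0.8, 1.8, 1, 1, g * 100, 100,
                                        se_i1 = 0, se_i2 = 0)))
  c1s <- vapply(res, `[[`, 0, "c1")
  c2s <- vapply(res, `[[`, 0, "c2")
  expect_true(all(diff(c1s) > 0))
  expect_true(all(diff(c2s) < 0))
  # gamma -> infinity: all mass in extrusion I
  expect_equal(res[[7]]$c1, 1.25, tolerance = 2e-3)
  # gamma = upsilon: C1 = alpha/2 exactly
  sym <- solve_concentrations(extrusion_pair(1, 0.8, 1.8, 1, 1, 125, 100,
                                             se_i1 = 0, se_i2 = 0))
  expect_equal(sym$c1, 1.25 / 2, tolerance = 1e-12)
})

test_that("simultaneous intensity rescaling leaves concentrations bit-identical", {
  p1 <- extrusion_pair(1.3, 0.7, 1.9, 40, 4, 220, 180, 0, 0)
  p2 <- extrusion_pair(1.3, 0.7, 1.9, 40, 4, 220 * 17.3, 180 * 17.3, 0, 0)
  r1 <- solve_concentrations(p1)
  r2 <- solve_concentrations(p2)
  expect_identical(r1$c1, r2$c1)
  expect_identical(r1$c2, r2$c2)
})

test_that("delta-method errors agree with a 100,000-draw Monte Carlo", {
  p <- extrusion_pair(1, 0.8, 1.8, 50, 5, 200, 250, se_i1 = 6, se_i2 = 8)
  res <- solve_concentrations(p)
  set.seed(77)
  i1 <- rnorm(1e5, 200, 6)
  i2 <- rnorm(1e5, 250, 8)
  g <- (i1 * 50) / (i2 * 5)
  c1 <- 1.25 * g / (g + 1.25)
  c2 <- 1.25 / (g + 1.25)
  expect_equal(res$se_c1, sd(c1), tolerance = 0.05)
  expect_equal(res$se_c2, sd(c2), tolerance = 0.05)
})

test_that("propagated SEs are first-order linear and handle degenerate cases", {
  p0 <- reference_pair(0, 0)
  r0 <- solve_concentrations(p0)
  expect_identical(r0$se_c1, 0)
  expect_identical(r0$se_c2, 0)
  ra <- solve_concentrations(reference_pair(2, 3))
  rb <- solve_concentrations(reference_pair(2 * 2.5, 3 * 2.5))
  expect_equal(rb$se_c1 / ra$se_c1, 2.5, tolerance = 1e-9)
  expect_equal(rb$se_c2 / ra$se_c2, 2.5, tolerance = 1e-9)
  # missing SEs propagate zeros with a flag
  pm <- extrusion_pair(1, 0.8, 1.8, 50, 5, 200, 250)
  expect_warning(rm <- solve_concentrations(pm), "SE missing")
  expect_true("missing_se" %in% rm$flags)
  expect_identical(rm$se_c1, 0)
})

test_that("mass and volume uncertainties enter the propagation when supplied", {
  p <- extrusion_pair(1, 0.8, 1.8, 50, 5, 200, 250, se_i1 = 0, se_i2 = 0,
                      se_m0 = 0.01)
  r <- solve_concentrations(p)
  # with exact intensities, SE(C1)/C1 = SE(M0)/M0 (C1 linear in alpha)
  expect_equal(r$se_c1 / r$c1, 0.01, tolerance = 1e-9)
  expect_equal(r$se_c2 / r$c2, 0.01, tolerance = 1e-9)
})

test_that("two preparations combine by the max of measurement and spread errors", {
  # identical inputs: spread vanishes, measurement error is attributed
  a <- aggregate_preparations(1.1, 1.1, 0.02, 0.02)
  expect_equal(a$mean, 1.1)
  expect_equal(a$sigma_prep, 0)
  expect_equal(a$uncertainty, sqrt(2 * 0.02^2) / 2)
  expect_identical(a$source, "measurement")
  # discrepant values with tiny measurement errors: spread dominates
  b <- aggregate_preparations(1.0, 1.2, 0.001, 0.001)
  expect_equal(b$mean, 1.1)
  expect_equal(b$sigma_prep, sqrt(0.1^2 + 0.1^2))
  expect_equal(b$uncertainty, b$sigma_prep)
  expect_identical(b$source, "spread")
  expect_gte(b$uncertainty, b$eps_meas)
  # works directly on solver results
  ra <- solve_concentrations(reference_pair(2, 3))
  rb <- solve_concentrations(reference_pair(3, 2))
  ab <- aggregate_preparations(ra, rb)
  expect_equal(ab$mean, (ra$c1 + rb$c1) / 2)
})

test_that("the Rayleigh-standard shortcut is an exact proportionality", {
  std <- standard_reference(r_std = 4e-4, c_std = 1.06, d_std = 50,
                            composition = "POPC", size_label = "50 nm")
  expect_equal(concentration_from_standard(4e-4, 50, std), 1.06)
  expect_equal(concentration_from_standard(8e-4, 50, std), 2.12)
  expect_equal(concentration_from_standard(4e-4, 100, std), 2.12)
  expect_error(standard_reference(0, 1, 1), "positive")
})

test_that("a standard characterized from one simulated preparation predicts another", {
  sim_std <- simulate_extrusion_experiment(cv = 0.005, seed = 301)
  res_std <- solve_concentrations(sim_std$pair)
  # characterize the standard by its undiluted intensity measure I1*d1
  std <- standard_reference(r_std = sim_std$pair$i1,
                            c_std = res_std$c1, d_std = sim_std$pair$d1)
  # an unknown preparation from the same generator at twice the mass
  sim_unk <- simulate_extrusion_experiment(m0 = 2, cv = 0.005, seed = 302)
  c_unk <- concentration_from_standard(sim_unk$pair$i1, sim_unk$pair$d1,
                                       std)
  expect_equal(c_unk, sim_unk$truth$c1, tolerance = 0.02)
})
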