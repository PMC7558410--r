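# Forward simulators for every input the pipeline consumes, with known
# ground truth. Defaults mirror the study conditions of the assay the
# package implements: about 1 mg of lipid extruded at about 1 mg/mL,
# extrusion-I and -II dilutions of 1:50 and 1:5, triplicate intensity
# readings with a few-percent coefficient of variation, a 532 nm laser at
# 90 degrees in water at 20 C, and vesicles of 50-200 nm with a
# polydispersity index near 0.06.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || !is.finite(seed))
      stop("'seed' must be a finite number")
    set.seed(as.integer(seed))
  }
  expr
}

#' Simulate a DLS correlogram from a size distribution
#'
#' Forward model g2(t) = B + beta [sum_i G_i exp(-Gamma_i t)]^2 on a
#' log-spaced lag grid spanning the decay, plus additive zero-mean
#' Gaussian noise. Deterministic given `seed`.
#'
#' @param dist A [size_distribution()] on the decay-rate grid.
#' @param B Baseline (default 1).
#' @param beta Intercept amplitude (default 0.8).
#' @param noise_sd Additive Gaussian noise standard deviation (default
#'   1e-3, a typical well-measured correlogram).
#' @param n_lags Number of lag points (default 200).
#' @param lag_range Optional length-2 lag range (us); the default spans
#'   the decay of every component carrying weight,
#'   `[0.01 / max(Gamma), 5 / min(Gamma)]`.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A [correlogram()].
#' @export
simulate_correlogram <- function(dist, B = 1, beta = 0.8, noise_sd = 1e-3,
                                 n_lags = 200, lag_range = NULL,
                                 seed = NULL) {
  stopifnot(inherits(dist, "size_distribution"))
  if (is.null(lag_range)) {
    carr <- dist$gamma_grid[dist$weights > 1e-6 * max(dist$weights)]
    lag_range <- c(0.01 / max(carr), 5 / min(carr))
  }
  t <- exp(seq(log(lag_range[1]), log(lag_range[2]), length.out = n_lags))
  g1 <- as.numeric(exp(-outer(t, dist$gamma_grid)) %*% dist$weights)
  g2 <- B + beta * g1^2
  .with_seed(seed, g2 <- g2 + stats::rnorm(n_lags, 0, noise_sd))
  correlogram(t, g2)
}

#' Simulate a correlogram at a given mean decay rate and width
#'
#' Forward model in the cumulants parametrization,
#' g2(t) = B + beta exp(-2 Gbar t) (1 + (mu2/2) t^2)^2, convenient for
#' generating data at a printed (Gbar, mu2) point. Deterministic given
#' `seed`.
#'
#' @param gamma_bar Mean decay rate (1/us).
#' @param mu2 Second moment of the decay-rate distribution (1/us^2).
#' @inheritParams simulate_correlogram
#' @return A [correlogram()].
#' @export
simulate_correlogram_cumulants <- function(gamma_bar, mu2 = 0, B = 1,
                                           beta = 0.8, noise_sd = 1e-3,
                                           n_lags = 200, lag_range = NULL,
                                           seed = NULL) {
  stopifnot(gamma_bar > 0, mu2 >= 0)
  if (is.null(lag_range)) lag_range <- c(0.01, 2.5) / gamma_bar
  t <- exp(seq(log(lag_range[1]), log(lag_range[2]), length.out = n_lags))
  g2 <- B + beta * exp(-2 * gamma_bar * t) * (1 + (mu2 / 2) * t^2)^2
  .with_seed(seed, g2 <- g2 + stats::rnorm(n_lags, 0, noise_sd))
  correlogram(t, g2)
}

# thin-shell form factor [sin(qR)/(qR)]^2 with R = D/2; q in 1/um, D in nm
.shell_form_factor <- function(diameter_nm, q_um) {
  x <- q_um * diameter_nm / 2 * 1e-3  # qR, dimensionless
  ifelse(x < 1e-8, 1, (sin(x) / x)^2)
}

#' Simulate a two-extrusion scattering experiment
#'
#' Generates an [extrusion_pair()] whose mass bookkeeping satisfies the
#' closure relation by construction, with scattered intensities from the
#' static-scattering forward model I = k Mw (C/d) P, where Mw and the
#' form factor P come from the thin-shell vesicle model averaged over the
#' supplied size distribution. Both samples share the distribution, so
#' their Mw and P are identical; the dead-volume solution shares the
#' extrusion-II concentration. Intensity replicates carry multiplicative
#' Gaussian noise of coefficient of variation `cv`.
#'
#' @param m0 Lipid mass in the film (mg); default 1.
#' @param v1 Extrusion-I recovered volume (mL); default 0.8.
#' @param vt Total loaded volume (mL); default 1.8.
#' @param residual_fraction Mass fraction not recovered in extrusion I
#'   (left for extrusion II plus dead volume), in [0, 1); default 0.15.
#' @param d1,d2 Dilutions before scattering; defaults 50 and 5.
#' @param dist Vesicle size distribution; default monodisperse at 90 nm
#'   under `cfg`.
#' @param cfg An [optical_config()].
#' @param shell A [shell_model()] supplying the mass-per-area constant.
#' @param k Instrument/contrast constant (a.u. mL/mg per unit Mw P);
#'   cancels in the assay, only sets the intensity scale.
#' @param cv Coefficient of variation of one intensity reading; default
#'   0.02.
#' @param n_rep Replicate readings per sample (default 3, averaged with
#'   SE = SD/sqrt(n) downstream).
#' @param seed Integer seed.
#' @return List with elements `pair` (the [extrusion_pair()]) and `truth`
#'   (class `simulation_truth`: true `c1`, `c2`, the distribution, `k`,
#'   `mw_Da`, `form_factor`, noise settings and the seed).
#' @examples
#' sim <- simulate_extrusion_experiment(seed = 42)
#' solve_concentrations(sim$pair)
#' sim$truth$c1
#' @export
simulate_extrusion_experiment <- function(m0 = 1, v1 = 0.8, vt = 1.8,
                                          residual_fraction = 0.15,
                                          d1 = 50, d2 = 5,
                                          dist = NULL,
                                          cfg = optical_config(),
                                          shell = shell_model(),
                                          k = 1e-6, cv = 0.02, n_rep = 3,
                                          seed = NULL) {
  if (!is.numeric(residual_fraction) || residual_fraction < 0 ||
      residual_fraction >= 1)
    stop("'residual_fraction' must lie in [0, 1)")
  if (vt <= v1) stop("'vt' must exceed 'v1'")
  if (is.null(dist))
    dist <- size_distribution(gamma_from_diameter(90, cfg), 1)

  c1 <- (1 - residual_fraction) * m0 / v1
  c2 <- residual_fraction * m0 / (vt - v1)

  q <- scattering_vector(cfg)
  d_nm <- stokes_einstein_diameter(dist$gamma_grid, cfg)
  mw <- sum(dist$weights * shell_mass(d_nm, shell))
  pth <- sum(dist$weights * .shell_form_factor(d_nm, q))

  i1_true <- k * mw * pth * c1 / d1
  i2_true <- k * mw * pth * c2 / d2

  reps <- .with_seed(seed, {
    list(i1 = i1_true * (1 + stats::rnorm(n_rep, 0, cv)),
         i2 = i2_true * (1 + stats::rnorm(n_rep, 0, cv)))
  })

  pair <- if (n_rep > 1L) {
    extrusion_pair(m0 = m0, v1 = v1, vt = vt, d1 = d1, d2 = d2,
                   i1 = reps$i1, i2 = reps$i2)
  } else {
    extrusion_pair(m0 = m0, v1 = v1, vt = vt, d1 = d1, d2 = d2,
                   i1 = reps$i1, i2 = reps$i2,
                   se_i1 = i1_true * cv, se_i2 = i2_true * cv)
  }

  truth <- structure(list(c1 = c1, c2 = c2, size_distribution = dist,
                          k = k, mw_Da = mw, form_factor = pth,
                          cv = cv, n_rep = n_rep,
                          i1_true = i1_true, i2_true = i2_true,
                          residual_fraction = residual_fraction,
                          seed = seed),
                     class = "simulation_truth")
  list(pair = pair, truth = truth)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("Simulation ground truth\n")
  cat(sprintf("  C1 = %.6g mg/mL, C2 = %.6g mg/mL\n", x$c1, x$c2))
  cat(sprintf("  Mw = %.4g Da, form factor = %.4g, k = %.3g\n",
              x$mw_Da, x$form_factor, x$k))
  cat(sprintf("  noise CV = %g, %d replicates, seed = %s\n",
              x$cv, x$n_rep, ifelse(is.null(x$seed), "none", x$seed)))
  invisible(x)
}

#' Simulate a spectrofluorimeter emission spectrum
#'
#' A Gaussian elastic band centered at the excitation wavelength, whose
#' integrated (baseline-free) area equals `intensity_equivalent`, sitting
#' on a flat baseline, plus additive Gaussian noise. Deterministic given
#' `seed`.
#'
#' @param intensity_equivalent Target peak area (a.u. nm), the simulated
#'   scattered-intensity measure.
#' @param lambda_ex Excitation wavelength (nm); default 532.
#' @param baseline Flat baseline level (a.u.); default 10.
#' @param peak_width Gaussian sigma of the elastic band (nm); default 1.5
#'   (of the order of the monochromator slit width).
#' @param noise_sd Additive noise sd (a.u.); default 0.5.
#' @param span_nm Half-width of the simulated wavelength window (nm);
#'   default 25.
#' @param step_nm Grid step (nm); default 0.25.
#' @param seed Integer seed.
#' @return An [emission_spectrum()].
#' @export
simulate_emission_spectrum <- function(intensity_equivalent,
                                       lambda_ex = 532, baseline = 10,
                                       peak_width = 1.5, noise_sd = 0.5,
                                       span_nm = 25, step_nm = 0.25,
                                       seed = NULL) {
  if (intensity_equivalent < 0) stop("'intensity_equivalent' must be >= 0")
  if (peak_width <= 0) stop("'peak_width' must be positive")
  lam <- seq(lambda_ex - span_nm, lambda_ex + span_nm, by = step_nm)
  amp <- intensity_equivalent / (peak_width * sqrt(2 * pi))
  y <- baseline + amp * exp(-(lam - lambda_ex)^2 / (2 * peak_width^2))
  .with_seed(seed, y <- y + stats::rnorm(length(lam), 0, noise_sd))
  emission_spectrum(lam, y, lambda_ex)
}

#' Simulate Stewart calibration standards
#'
#' Absorbances generated from a straight line plus Gaussian noise, read
#' in `n_rep` replicates per standard; each standard reports the
#' replicate mean and SE = SD/sqrt(n_rep). The default concentration grid
#' spans the assay's linear regime, 0.005-0.050 mg/mL.
#'
#' @param true_slope Calibration slope (absorbance per mg/mL); default 20.
#' @param true_intercept Calibration intercept (absorbance); default 0.05.
#' @param conc_grid Standard concentrations (mg/mL); default 10 evenly
#'   spaced points on [0.005, 0.050].
#' @param noise_sd Absorbance noise sd per reading; default 0.01.
#' @param n_rep Replicate readings per standard; default 3.
#' @param seed Integer seed.
#' @return Data frame with columns `conc_mg_ml`, `absorbance`, `se`,
#'   ready for [fit_calibration()].
#' @export
simulate_stewart_standards <- function(true_slope = 20,
                                       true_intercept = 0.05,
                                       conc_grid = seq(0.005, 0.050,
                                                       length.out = 10),
                                       noise_sd = 0.01, n_rep = 3,
                                       seed = NULL) {
  if (any(conc_grid <= 0)) stop("'conc_grid' must be positive")
  if (n_rep < 1) stop("'n_rep' must be at least 1")
  .with_seed(seed, {
    means <- numeric(length(conc_grid))
    ses <- numeric(length(conc_grid))
    for (i in seq_along(conc_grid)) {
      reads <- true_slope * conc_grid[i] + true_intercept +
        stats::rnorm(n_rep, 0, noise_sd)
      means[i] <- mean(reads)
      ses[i] <- if (n_rep > 1L) stats::sd(reads) / sqrt(n_rep)
                else noise_sd
    }
    data.frame(conc_mg_ml = conc_grid, absorbance = means, se = ses)
  })
}
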