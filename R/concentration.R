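# Two-extrusion mass-closure concentration assay.
#
# The static scattered intensity of a dilute vesicle dispersion is
# I = k Mw C P, with k the instrument/contrast constant, Mw the weight
# averaged vesicle mass, C the weight concentration and P the form
# factor. Both extrusion samples share the same size distribution, hence
# the same Mw and P, so the ratio of dilution-corrected intensities gives
# the concentration ratio directly:
#
#   gamma = (I1 d1)/(I2 d2) = C1/C2
#
# Mass conservation over the preparation closes the system:
#
#   M0 = C1 V1 + C2 (VT - V1)
#
# (the second-extrusion and dead-volume solutions are assumed to share
# concentration C2). With alpha = M0/V1 and upsilon = (VT - V1)/V1 the
# closed-form solution is C2 = alpha/(gamma + upsilon) and
# C1 = alpha gamma/(gamma + upsilon).

#' Extrusion bookkeeping and intensity record
#'
#' Everything the mass-closure solver consumes: the weighed lipid mass,
#' recovered volumes, dilutions and buffer-subtracted scattered
#' intensities of the two sequential extrusion samples. Intensities may be
#' given either as a single value with a standard error, or as a vector of
#' replicate readings which are averaged with SE = SD/sqrt(n). An optional
#' buffer reading (same convention) is subtracted from both samples with
#' its SE added in quadrature.
#'
#' @param m0 Total lipid mass weighed into the film (mg).
#' @param v1 Recovered volume after extrusion I (mL).
#' @param vt Total volume loaded into the extruder, including the rinse
#'   added before extrusion II (mL); must exceed `v1`.
#' @param d1,d2 Dilution factors applied before the scattering measurement
#'   (>= 1).
#' @param i1,i2 Scattered intensities of the diluted extrusion-I and -II
#'   samples (arbitrary units, same setup for both): scalars or replicate
#'   vectors.
#' @param se_i1,se_i2 Standard errors of `i1`, `i2`; ignored (recomputed)
#'   when replicates are supplied. `NA` means unknown.
#' @param v2 Recovered volume after extrusion II (mL), optional; used only
#'   to check the dead volume `vt - v1 - v2 >= 0`.
#' @param buffer Optional buffer intensity to subtract (scalar or
#'   replicate vector).
#' @param se_buffer Standard error of the buffer reading (ignored when
#'   `buffer` has replicates).
#' @param se_m0,se_v1,se_vt Optional standard errors on mass and volumes;
#'   default 0 (read off the balance and the syringe scale, treated as
#'   exact).
#' @return An object of class `extrusion_pair`.
#' @examples
#' extrusion_pair(m0 = 1, v1 = 0.8, vt = 1.8, d1 = 50, d2 = 5,
#'                i1 = c(199, 201, 200), i2 = c(249, 251, 250))
#' @export
extrusion_pair <- function(m0, v1, vt, d1, d2, i1, i2,
                           se_i1 = NA, se_i2 = NA, v2 = NULL,
                           buffer = NULL, se_buffer = 0,
                           se_m0 = 0, se_v1 = 0, se_vt = 0) {
  for (nm in c("m0", "v1", "vt", "d1", "d2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single positive number")
  }
  if (d1 < 1 || d2 < 1) stop("dilution factors must be >= 1")
  if (vt <= v1) stop("'vt' must exceed 'v1'")
  if (!is.null(v2)) {
    if (!is.numeric(v2) || v2 <= 0) stop("'v2' must be positive")
    if (vt - v1 - v2 < -sqrt(.Machine$double.eps))
      stop("negative dead volume: vt must be at least v1 + v2")
  }

  sub <- .summarize_intensity(buffer, se_buffer, "buffer", allow_null = TRUE)
  s1 <- .summarize_intensity(i1, se_i1, "i1")
  s2 <- .summarize_intensity(i2, se_i2, "i2")
  if (!is.null(sub)) {
    s1 <- list(mean = s1$mean - sub$mean, se = sqrt(s1$se^2 + sub$se^2))
    s2 <- list(mean = s2$mean - sub$mean, se = sqrt(s2$se^2 + sub$se^2))
  }
  if (s1$mean <= 0 || s2$mean <= 0)
    stop("buffer-subtracted intensities must be positive")

  structure(list(m0 = m0, v1 = v1, v2 = v2, vt = vt, d1 = d1, d2 = d2,
                 i1 = s1$mean, i2 = s2$mean, se_i1 = s1$se, se_i2 = s2$se,
                 se_m0 = se_m0, se_v1 = se_v1, se_vt = se_vt),
            class = "extrusion_pair")
}

.summarize_intensity <- function(x, se, what, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(NULL)
    stop("'", what, "' is required")
  }
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'", what, "' must be finite numeric")
  if (length(x) > 1L) {
    list(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
  } else {
    list(mean = x, se = if (is.na(se)) NA_real_ else se)
  }
}

#' @export
print.extrusion_pair <- function(x, ...) {
  cat("Extrusion pair\n")
  cat(sprintf("  M0 = %g mg, V1 = %g mL, VT = %g mL (dead+II volume %g mL)\n",
              x$m0, x$v1, x$vt, x$vt - x$v1))
  cat(sprintf("  I1 = %g +- %g (d1 = %g);  I2 = %g +- %g (d2 = %g)\n",
              x$i1, x$se_i1, x$d1, x$i2, x$se_i2, x$d2))
  cat(sprintf("  gamma = %.6g\n", compute_gamma(x)))
  invisible(x)
}

#' Dilution-corrected intensity ratio
#'
#' gamma = (I1 d1)/(I2 d2), equal to the concentration ratio C1/C2 because
#' vesicle mass and form factor cancel between the two samples. Invariant
#' under any common rescaling of the two intensities, so any instrument
#' (goniometer counts, Rayleigh ratios, elastic-peak areas) can supply
#' them, as long as both samples are measured in the same conditions.
#'
#' @param pair An [extrusion_pair()], or a raw intensity `i1` when all of
#'   `d1`, `i2`, `d2` are given.
#' @param d1,i2,d2 Dilutions and second intensity for the raw-value form.
#' @return The dimensionless ratio gamma.
#' @examples
#' compute_gamma(200, 50, 250, 5)  # 8
#' @export
compute_gamma <- function(pair, d1 = NULL, i2 = NULL, d2 = NULL) {
  if (inherits(pair, "extrusion_pair")) {
    i1 <- pair$i1; d1 <- pair$d1; i2 <- pair$i2; d2 <- pair$d2
  } else {
    i1 <- pair
    if (is.null(d1) || is.null(i2) || is.null(d2))
      stop("supply an extrusion_pair or all of i1, d1, i2, d2")
  }
  if (!is.finite(i2 * d2) || i2 * d2 <= 0)
    stop("extrusion-II measurement invalid: I2 * d2 must be positive")
  (i1 * d1) / (i2 * d2)
}

#' Solve the two-extrusion mass-closure system
#'
#' Closed-form solution for the weight concentrations of the extrusion-I
#' and extrusion-II samples from the dilution-corrected intensity ratio
#' and the conservation of the weighed lipid mass, with first-order
#' (delta-method) standard errors.
#'
#' @param pair An [extrusion_pair()].
#' @return An object of class `concentration_result`: list with `c1`, `c2`
#'   (mg/mL), `se_c1`, `se_c2`, the intermediates `alpha` (M0/V1),
#'   `upsilon` ((VT-V1)/V1) and `gamma` (I1 d1 / I2 d2), `closure_residual`
#'   (relative), `flags` and the input `pair`.
#' @details Standard errors propagate the intensity SEs (and any optional
#'   mass/volume SEs) through the closed form to first order. Missing
#'   intensity SEs propagate as zeros with a `"missing_se"` flag. A
#'   `"c1_exceeds_alpha"` flag signals inconsistent inputs (C1 > M0/V1 is
#'   impossible under mass conservation).
#' @examples
#' p <- extrusion_pair(m0 = 1, v1 = 0.8, vt = 1.8, d1 = 50, d2 = 5,
#'                     i1 = 200, i2 = 250, se_i1 = 4, se_i2 = 5)
#' solve_concentrations(p)
#' @export
solve_concentrations <- function(pair) {
  stopifnot(inherits(pair, "extrusion_pair"))
  gamma <- compute_gamma(pair)
  alpha <- pair$m0 / pair$v1
  upsilon <- (pair$vt - pair$v1) / pair$v1
  c2 <- alpha / (gamma + upsilon)
  c1 <- alpha * gamma / (gamma + upsilon)

  flags <- character(0)
  if (c1 > alpha * (1 + 1e-12)) flags <- c(flags, "c1_exceeds_alpha")
  # extrusion II indistinguishable from noise: gamma (and hence C1) is
  # still defined but C2 is effectively unconstrained
  if (!is.na(pair$se_i2) && pair$se_i2 > 0 && pair$i2 <= 2 * pair$se_i2)
    flags <- c(flags, "i2_below_noise")

  err <- propagate_errors(pair)
  flags <- c(flags, err$flags)

  closure <- (c1 * pair$v1 + c2 * (pair$vt - pair$v1) - pair$m0) / pair$m0

  structure(list(c1 = c1, c2 = c2, se_c1 = err$se_c1, se_c2 = err$se_c2,
                 alpha = alpha, upsilon = upsilon, gamma = gamma,
                 closure_residual = closure, flags = flags, pair = pair),
            class = "concentration_result")
}

#' First-order error propagation for the mass-closure solution
#'
#' Delta-method standard errors on (C1, C2) from the standard errors of
#' the two intensities and, when supplied, of M0, V1 and VT. The gradient
#' of the closed form is evaluated analytically.
#'
#' @param pair An [extrusion_pair()].
#' @return List with `se_c1`, `se_c2` and `flags` (contains
#'   `"missing_se"` when intensity SEs were unavailable and treated as 0).
#' @export
propagate_errors <- function(pair) {
  stopifnot(inherits(pair, "extrusion_pair"))
  flags <- character(0)
  se1 <- pair$se_i1; se2 <- pair$se_i2
  if (is.na(se1) || is.na(se2)) {
    flags <- "missing_se"
    if (is.na(se1)) se1 <- 0
    if (is.na(se2)) se2 <- 0
  }
  gamma <- compute_gamma(pair)
  alpha <- pair$m0 / pair$v1
  upsilon <- (pair$vt - pair$v1) / pair$v1
  gu <- gamma + upsilon

  # dC/dgamma
  dc1_dg <- alpha * upsilon / gu^2
  dc2_dg <- -alpha / gu^2
  # gamma sensitivities to the intensities
  dg_di1 <- gamma / pair$i1
  dg_di2 <- -gamma / pair$i2
  var_gamma <- (dg_di1 * se1)^2 + (dg_di2 * se2)^2

  # optional mass/volume contributions via alpha and upsilon
  # C1 = alpha*gamma/gu, C2 = alpha/gu with upsilon = vt/v1 - 1
  dc1_da <- gamma / gu; dc2_da <- 1 / gu
  dc1_du <- -alpha * gamma / gu^2; dc2_du <- -alpha / gu^2
  da_dm0 <- 1 / pair$v1
  da_dv1 <- -pair$m0 / pair$v1^2
  du_dv1 <- -pair$vt / pair$v1^2
  du_dvt <- 1 / pair$v1

  var_c1 <- dc1_dg^2 * var_gamma +
    (dc1_da * da_dm0 * pair$se_m0)^2 +
    ((dc1_da * da_dv1 + dc1_du * du_dv1) * pair$se_v1)^2 +
    (dc1_du * du_dvt * pair$se_vt)^2
  var_c2 <- dc2_dg^2 * var_gamma +
    (dc2_da * da_dm0 * pair$se_m0)^2 +
    ((dc2_da * da_dv1 + dc2_du * du_dv1) * pair$se_v1)^2 +
    (dc2_du * du_dvt * pair$se_vt)^2

  if (length(flags)) warning("intensity SE missing; propagated as zero")
  list(se_c1 = sqrt(var_c1), se_c2 = sqrt(var_c2), flags = flags)
}

#' @export
print.concentration_result <- function(x, ...) {
  cat("Mass-closure concentration result\n")
  cat(sprintf("  C1 = %.6g +- %.3g mg/mL (extrusion I)\n", x$c1, x$se_c1))
  cat(sprintf("  C2 = %.6g +- %.3g mg/mL (extrusion II + dead volume)\n",
              x$c2, x$se_c2))
  cat(sprintf("  alpha = %.6g mg/mL, upsilon = %.6g, gamma = %.6g\n",
              x$alpha, x$upsilon, x$gamma))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.concentration_result <- function(object, ...) {
  print(object)
  cat(sprintf("  closure residual (relative): %.3g\n",
              object$closure_residual))
  cat(sprintf("  recovered mass fractions: %.4g (I), %.4g (II + dead)\n",
              object$c1 * object$pair$v1 / object$pair$m0,
              object$c2 * (object$pair$vt - object$pair$v1) / object$pair$m0))
  invisible(object)
}

#' @export
coef.concentration_result <- function(object, ...) {
  c(c1 = object$c1, c2 = object$c2)
}

#' Combine two independent preparations of the same sample
#'
#' Averages the concentrations of two preparations and attributes the
#' larger of two uncertainties: the combined measurement error
#' `eps = sqrt(eps_A^2 + eps_B^2) / 2` (the standard error of the mean of
#' two independent measurements) and the preparation spread
#' `sigma = sqrt(dx_A^2 + dx_B^2)` with `dx = x - mean`. The spread term
#' dominates when the two preparations disagree by more than their
#' individual measurement errors can explain.
#'
#' @param x_a,x_b The two concentration values (or any paired scalar
#'   estimates), or two [solve_concentrations()] results, in which case
#'   their `c1` values and SEs are used.
#' @param eps_a,eps_b Propagated measurement errors of the two values
#'   (ignored when results are supplied).
#' @param component Which concentration to aggregate when results are
#'   supplied: `"c1"` (default) or `"c2"`.
#' @return List with `mean`, `uncertainty`, `eps_meas` (combined
#'   measurement error), `sigma_prep` (spread term) and `source`
#'   (`"measurement"` or `"spread"`, whichever was attributed).
#' @examples
#' aggregate_preparations(1.0, 1.2, 0.01, 0.01)
#' @export
aggregate_preparations <- function(x_a, x_b, eps_a = NULL, eps_b = NULL,
                                   component = c("c1", "c2")) {
  component <- match.arg(component)
  if (inherits(x_a, "concentration_result")) {
    stopifnot(inherits(x_b, "concentration_result"))
    eps_a <- if (component == "c1") x_a$se_c1 else x_a$se_c2
    eps_b <- if (component == "c1") x_b$se_c1 else x_b$se_c2
    x_a <- x_a[[component]]
    x_b <- x_b[[component]]
  }
  stopifnot(is.numeric(x_a), is.numeric(x_b),
            is.numeric(eps_a), is.numeric(eps_b))
  m <- (x_a + x_b) / 2
  eps_ab <- sqrt(eps_a^2 + eps_b^2) / 2
  sigma_ab <- sqrt((x_a - m)^2 + (x_b - m)^2)
  list(mean = m, uncertainty = max(eps_ab, sigma_ab),
       eps_meas = eps_ab, sigma_prep = sigma_ab,
       source = if (sigma_ab > eps_ab) "spread" else "measurement")
}

#' Characterized scattering standard
#'
#' A previously measured dispersion of known composition, size class and
#' weight concentration, with its Rayleigh ratio (or raw intensity on the
#' same setup) at a stated angle.
#'
#' @param r_std Rayleigh ratio (1/cm) or intensity of the standard.
#' @param c_std Weight concentration of the standard (mg/mL).
#' @param d_std Dilution at which `r_std` was measured.
#' @param composition,size_label Descriptive labels used only for
#'   bookkeeping; the caller is responsible for matching them to the
#'   unknown sample.
#' @return An object of class `standard_reference`.
#' @export
standard_reference <- function(r_std, c_std, d_std = 1,
                               composition = NA_character_,
                               size_label = NA_character_) {
  vals <- c(r_std, c_std, d_std)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("'r_std', 'c_std' and 'd_std' must be positive")
  structure(list(r_std = r_std, c_std = c_std, d_std = d_std,
                 composition = composition, size_label = size_label),
            class = "standard_reference")
}

#' @export
print.standard_reference <- function(x, ...) {
  cat(sprintf("Scattering standard: C = %g mg/mL at d = %g, R = %g\n",
              x$c_std, x$d_std, x$r_std))
  if (!is.na(x$composition)) cat("  composition:", x$composition, "\n")
  if (!is.na(x$size_label)) cat("  size:", x$size_label, "\n")
  invisible(x)
}

#' Concentration of a repeat preparation from a characterized standard
#'
#' Once a standard of identical composition and size distribution has
#' been characterized (Rayleigh ratio and concentration), a later
#' preparation's concentration follows from one intensity measurement:
#' C = C_std (d / d_std) (R / R_std). Sample and standard must be measured
#' at the same angle; the caller asserts the similarity (a DLS comparison
#' of the two distributions is the recommended check).
#'
#' @param r Measured Rayleigh ratio or intensity of the unknown (same
#'   units/setup as the standard).
#' @param d Dilution of the unknown.
#' @param std A [standard_reference()].
#' @return Weight concentration (mg/mL).
#' @export
concentration_from_standard <- function(r, d, std) {
  stopifnot(inherits(std, "standard_reference"))
  if (!is.numeric(r) || any(!is.finite(r)) || any(r < 0))
    stop("'r' must be non-negative and finite")
  if (!is.numeric(d) || any(d < 1)) stop("'d' must be >= 1")
  if (std$r_std == 0) stop("standard Rayleigh ratio must be non-zero")
  std$c_std * (d / std$d_std) * (r / std$r_std)
}
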