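# Stewart colorimetric phospholipid assay: weighted linear calibration of
# absorbance at 485 nm against standard concentration, and inverse
# prediction of an unknown from its measured absorbance.

#' Fit a Stewart calibration curve
#'
#' Weighted linear least squares (weights proportional to 1/SE^2) of
#' absorbance on standard concentration. Beer-Lambert linearity justifies
#' the straight line; the intercept is fitted (not forced through the
#' origin) to absorb any constant blank, with a forced-origin option.
#'
#' @param standards Data frame with columns `conc_mg_ml`, `absorbance`
#'   and optionally `se` (standard error of each absorbance). Without
#'   `se` (or with any non-positive value) the fit falls back to ordinary
#'   least squares.
#' @param through_origin Force a zero intercept (default `FALSE`).
#' @return An object of class `calibration_curve`: list with `slope`,
#'   `intercept`, their `se`, the 2x2 parameter covariance `vcov`
#'   (ordered intercept, slope; degenerate row/column of zeros when
#'   forced through the origin), `r_squared`, `valid_range` (range of the
#'   standard concentrations), `weighted` flag, the `standards` table and
#'   the underlying `lm` fit.
#' @details Standards must number at least 3 with strictly positive,
#'   non-degenerate concentrations. The matrix-specific curves for
#'   different lipid mixtures (cholesterol does not react, and different
#'   phospholipids react differently) are simply separate curves fitted
#'   from matrix-matched standards; store the composition in a label on
#'   the standards table if needed.
#' @examples
#' std <- simulate_stewart_standards(20, 0.05, noise_sd = 0.005, seed = 1)
#' fit_calibration(std)
#' @export
fit_calibration <- function(standards, through_origin = FALSE) {
  req <- c("conc_mg_ml", "absorbance")
  if (!is.data.frame(standards) || !all(req %in% names(standards)))
    stop("'standards' needs columns conc_mg_ml and absorbance")
  x <- standards$conc_mg_ml
  y <- standards$absorbance
  if (length(x) < 3L) stop("at least 3 calibration standards are required")
  if (any(!is.finite(x)) || any(x <= 0))
    stop("standard concentrations must be positive")
  if (length(unique(x)) < 2L)
    stop("degenerate design: all standards at the same concentration")

  w <- NULL
  weighted <- FALSE
  if ("se" %in% names(standards)) {
    se <- standards$se
    if (all(is.finite(se)) && all(se > 0)) {
      w <- 1 / se^2
      weighted <- TRUE
    }
  }
  fit <- if (through_origin) stats::lm(y ~ x + 0, weights = w)
         else stats::lm(y ~ x, weights = w)

  cf <- stats::coef(fit)
  vc <- suppressWarnings(stats::vcov(fit))  # noiseless fits are legal here
  if (through_origin) {
    slope <- cf[["x"]]; intercept <- 0
    se_slope <- sqrt(vc[1, 1]); se_intercept <- 0
    V <- matrix(c(0, 0, 0, vc[1, 1]), 2, 2,
                dimnames = list(c("intercept", "slope"),
                                c("intercept", "slope")))
  } else {
    slope <- cf[["x"]]; intercept <- cf[["(Intercept)"]]
    se_slope <- sqrt(vc["x", "x"]); se_intercept <- sqrt(vc[1, 1])
    V <- vc
    dimnames(V) <- list(c("intercept", "slope"), c("intercept", "slope"))
  }
  if (abs(slope) < .Machine$double.eps^0.5)
    stop("degenerate calibration: slope is numerically zero")

  r2 <- suppressWarnings(summary(fit)$r.squared)

  structure(list(slope = slope, intercept = intercept,
                 se_slope = se_slope, se_intercept = se_intercept,
                 vcov = V, r_squared = r2,
                 valid_range = range(x), weighted = weighted,
                 through_origin = through_origin,
                 standards = standards, lm_fit = fit),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Stewart calibration curve",
      if (x$weighted) "(error-weighted fit)" else "(unweighted fit)", "\n")
  cat(sprintf("  A = %.6g * C + %.6g\n", x$slope, x$intercept))
  cat(sprintf("  slope SE = %.3g, intercept SE = %.3g, R^2 = %.5g\n",
              x$se_slope, x$se_intercept, x$r_squared))
  cat(sprintf("  valid range: %.4g - %.4g mg/mL (%d standards)\n",
              x$valid_range[1], x$valid_range[2], nrow(x$standards)))
  invisible(x)
}

#' @export
coef.calibration_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
vcov.calibration_curve <- function(object, ...) object$vcov

#' @export
plot.calibration_curve <- function(x, ...) {
  graphics::plot(x$standards$conc_mg_ml, x$standards$absorbance,
                 xlab = "concentration (mg/mL)", ylab = "absorbance", ...)
  graphics::abline(a = x$intercept, b = x$slope, col = 2)
}

#' Inverse prediction from a Stewart calibration curve
#'
#' Maps a measured absorbance (average of replicate readings, with its
#' standard error) back to sample concentration:
#' C = dilution (A - intercept) / slope, with the SE from first-order
#' propagation of the absorbance error and the calibration-parameter
#' covariance.
#'
#' @param curve A [fit_calibration()] result.
#' @param abs_mean Measured absorbance.
#' @param abs_se Standard error of the absorbance (default 0).
#' @param dilution Dilution factor applied to the sample before the assay
#'   (default 1).
#' @return List with `conc` (mg/mL), `se` and `extrapolated` (`TRUE`,
#'   with a warning, when the absorbance maps outside the calibrated
#'   concentration range).
#' @examples
#' cal <- fit_calibration(simulate_stewart_standards(seed = 1))
#' predict_concentration(cal, abs_mean = 0.5, abs_se = 0.01, dilution = 41)
#' @export
predict_concentration <- function(curve, abs_mean, abs_se = 0, dilution = 1) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.numeric(abs_mean) || !is.finite(abs_mean))
    stop("'abs_mean' must be a finite number")
  if (dilution < 1) stop("'dilution' must be >= 1")
  s <- curve$slope; a <- curve$intercept
  c_undil <- (abs_mean - a) / s
  conc <- dilution * c_undil

  extrapolated <- c_undil < curve$valid_range[1] ||
    c_undil > curve$valid_range[2]
  if (extrapolated)
    warning(sprintf(
      "absorbance maps to %.4g mg/mL, outside the calibrated range [%.4g, %.4g]",
      c_undil, curve$valid_range[1], curve$valid_range[2]))

  # gradient wrt (A, intercept, slope)
  dA <- dilution / s
  grad_ab <- c(-dilution / s, -dilution * (abs_mean - a) / s^2)
  var_fit <- drop(t(grad_ab) %*% curve$vcov %*% grad_ab)
  se <- sqrt((dA * abs_se)^2 + max(var_fit, 0))

  list(conc = conc, se = se, extrapolated = extrapolated)
}

#' Convenience predict method for calibration curves
#'
#' With `newdata` absent, returns fitted absorbances for the standards.
#' With a numeric `newdata`, treats it as concentrations and returns the
#' calibration line evaluated there. Inverse prediction (absorbance to
#' concentration) goes through [predict_concentration()].
#'
#' @param object A `calibration_curve`.
#' @param newdata Optional numeric vector of concentrations (mg/mL).
#' @param ... Unused.
#' @export
predict.calibration_curve <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$standards$conc_mg_ml
  object$intercept + object$slope * newdata
}
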