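# Cumulants analysis of DLS correlograms.
#
# Model: g2(t) = B + beta * exp(-2 Gbar t) * (1 + (mu2/2) t^2)^2,
# the second-order cumulants expansion of the field correlation function
# squared, written in the (non-linearized) bracket form. Order 1 drops the
# mu2 term. Gbar is the intensity-weighted mean decay rate (1/us), mu2 the
# second central moment of the decay-rate distribution (1/us^2); their
# ratio PI = mu2 / Gbar^2 is the polydispersity index.

#' Cumulants fit of an intensity autocorrelation function
#'
#' Fits g2(t) = B + beta exp(-2 Gbar t) (1 + (mu2/2) t^2)^2 by
#' Levenberg-Marquardt least squares (uniform weights). The baseline B is
#' started at the mean of g2 over the last 10% of lags and refined inside
#' the fit; Gbar is started from a log-linear regression of
#' ln[(g2 - B)/beta] over the first decade of the decay; mu2 starts at 0.
#'
#' @param c A [correlogram()].
#' @param order Expansion order, 1 or 2. Order 1 fixes mu2 = 0.
#' @return An object of class `cumulants_fit`: a list with elements
#'   `coefficients` (B, beta, gamma_bar, mu2), `se` (standard errors from
#'   the fit covariance), `vcov`, `pi` (mu2/gamma_bar^2) and `pi_se`,
#'   `fitted`, `residuals`, `correlogram`, `order`, `convergence` (message
#'   and iteration count) and `flags` (character vector; contains
#'   `"low_intercept"` when the fitted beta < 0.05, `"at_bound"` when a
#'   constrained parameter sits on its bound).
#' @examples
#' cfg <- optical_config()
#' cor <- simulate_correlogram_cumulants(0.0024, 5.5e-7, noise_sd = 1e-3,
#'                                       seed = 7)
#' fit <- fit_cumulants(cor)
#' coef(fit)["gamma_bar"]
#' stokes_einstein_diameter(coef(fit)[["gamma_bar"]], cfg)
#' @export
fit_cumulants <- function(c, order = 2) {
  stopifnot(inherits(c, "correlogram"))
  if (!order %in% c(1, 2)) stop("'order' must be 1 or 2")
  t <- c$lag_us
  y <- c$g2

  B0 <- .estimate_baseline(c)
  amp <- y - B0
  if (max(amp) <= 10 * stats::sd(utils::tail(y, max(3, nrow(c) %/% 10))) &&
      max(amp) <= 1e-4)
    stop("no visible decay: g2 range does not rise above the noise floor")
  beta0 <- max(amp[1], 1e-3)

  # log-linear start for Gbar over the first decade of decay
  pos <- which(amp > 0.1 * beta0 & amp < beta0 * 1.001)
  if (length(pos) < 3L) pos <- which(amp > 0)[seq_len(min(5L, sum(amp > 0)))]
  lf <- stats::lm(log(amp[pos]) ~ t[pos])
  g0 <- max(-stats::coef(lf)[[2]] / 2, 1e-8)

  model <- function(p, t) {
    poly <- 1 + (p["mu2"] / 2) * t^2
    p["B"] + p["beta"] * exp(-2 * p["gamma_bar"] * t) * poly^2
  }
  resid_fn <- function(p, t, y) y - model(p, t)

  start <- c(B = B0, beta = beta0, gamma_bar = g0, mu2 = 0)
  lower <- c(B = -Inf, beta = 1e-12, gamma_bar = 1e-12, mu2 = 0)
  upper <- c(B = Inf, beta = Inf, gamma_bar = Inf,
             mu2 = if (order == 1) 0 else Inf)
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid_fn, t = t, y = y,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  if (fit$info %in% c(0, 5, 9))
    stop("cumulants fit did not converge: ", fit$message,
         " (", fit$niter, " iterations)")
  est <- fit$par

  # covariance of the estimates: sigma^2 * (J'J)^-1, dropping the pinned
  # mu2 column for an order-1 fit
  free <- if (order == 1) c("B", "beta", "gamma_bar") else names(est)
  dof <- length(y) - length(free)
  s2 <- fit$deviance / max(dof, 1L)
  h <- fit$hessian[free, free, drop = FALSE]
  vc <- tryCatch(s2 * solve(h), error = function(e) {
    matrix(NA_real_, length(free), length(free),
           dimnames = list(free, free))
  })
  se <- stats::setNames(rep(0, 4L), names(est))
  se[free] <- sqrt(pmax(diag(vc), 0))

  flags <- character(0)
  if (est[["beta"]] < 0.05) flags <- c(flags, "low_intercept")
  if (order == 2 && est[["mu2"]] <= lower[["mu2"]] + 1e-15 * abs(est[["mu2"]] + 1))
    flags <- c(flags, "at_bound")

  gb <- est[["gamma_bar"]]; m2 <- est[["mu2"]]
  pi_val <- m2 / gb^2
  # delta method on PI = mu2/gb^2 using the joint covariance
  pi_se <- if (order == 2 && all(is.finite(vc))) {
    gr <- c(gamma_bar = -2 * m2 / gb^3, mu2 = 1 / gb^2)
    vv <- vc[c("gamma_bar", "mu2"), c("gamma_bar", "mu2")]
    sqrt(max(drop(t(gr) %*% vv %*% gr), 0))
  } else 0

  structure(list(coefficients = est, se = se, vcov = vc,
                 pi = pi_val, pi_se = pi_se,
                 fitted = model(est, t), residuals = as.numeric(fit$fvec),
                 correlogram = c, order = order,
                 convergence = list(message = fit$message,
                                    iterations = fit$niter,
                                    deviance = fit$deviance),
                 flags = flags),
            class = "cumulants_fit")
}

#' @export
print.cumulants_fit <- function(x, ...) {
  cat(sprintf("Cumulants fit (order %d)\n", x$order))
  cm <- x$coefficients
  cat(sprintf("  B         = %.6g +- %.2g\n", cm[["B"]], x$se[["B"]]))
  cat(sprintf("  beta      = %.6g +- %.2g\n", cm[["beta"]], x$se[["beta"]]))
  cat(sprintf("  Gamma_bar = %.6g +- %.2g 1/us\n",
              cm[["gamma_bar"]], x$se[["gamma_bar"]]))
  if (x$order == 2)
    cat(sprintf("  mu2       = %.6g +- %.2g 1/us^2\n",
                cm[["mu2"]], x$se[["mu2"]]))
  cat(sprintf("  PI        = %.4g\n", x$pi))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cumulants_fit <- function(object, cfg = NULL, ...) {
  out <- list(fit = object,
              diameter_nm = if (!is.null(cfg))
                stokes_einstein_diameter(object$coefficients[["gamma_bar"]],
                                         cfg) else NA_real_)
  class(out) <- "summary.cumulants_fit"
  out
}

#' @export
print.summary.cumulants_fit <- function(x, ...) {
  print(x$fit)
  if (is.finite(x$diameter_nm))
    cat(sprintf("  D_h(cum)  = %.4g nm\n", x$diameter_nm))
  cat(sprintf("  residual sd = %.3g over %d lags (%s, %d iterations)\n",
              stats::sd(x$fit$residuals), nrow(x$fit$correlogram),
              x$fit$convergence$message, x$fit$convergence$iterations))
  invisible(x)
}

#' @export
coef.cumulants_fit <- function(object, ...) object$coefficients

#' @export
vcov.cumulants_fit <- function(object, ...) object$vcov

#' @export
residuals.cumulants_fit <- function(object, ...) object$residuals

#' @export
fitted.cumulants_fit <- function(object, ...) object$fitted

#' @export
predict.cumulants_fit <- function(object, lag_us = NULL, ...) {
  if (is.null(lag_us)) return(object$fitted)
  p <- object$coefficients
  poly <- 1 + (p[["mu2"]] / 2) * lag_us^2
  p[["B"]] + p[["beta"]] * exp(-2 * p[["gamma_bar"]] * lag_us) * poly^2
}

#' @export
plot.cumulants_fit <- function(x, ...) {
  graphics::plot(x$correlogram$lag_us, x$correlogram$g2, log = "x",
                 xlab = "lag time (us)", ylab = "g2(t)", ...)
  graphics::lines(x$correlogram$lag_us, x$fitted, col = 2)
}
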