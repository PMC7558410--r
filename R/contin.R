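# Regularized inverse Laplace transform of a correlogram (CONTIN-like),
# recovering the intensity-weighted decay-rate distribution G(Gamma) in
# g2(t) = B + beta [ integral G(Gamma) exp(-Gamma t) dGamma ]^2.
#
# Implementation: the baseline B is started at the mean of the correlogram
# tail and refined by a one-dimensional search minimizing the g2-domain
# reconstruction residual (the inversion is quite sensitive to B: an
# overestimated baseline truncates the slow components); the square root
# of the normalized, baseline-subtracted correlogram is then fitted as
# sum_i G_i exp(-Gamma_i t) by non-negative least squares with a
# squared-second-difference (smoothness) penalty on G. The penalty weight
# lambda is either given or chosen by the corner of the L-curve on a
# log-spaced lambda grid.

#' Intensity-weighted size distribution
#'
#' Non-negative weights on a strictly increasing decay-rate grid,
#' normalized to unit sum.
#'
#' @param gamma_grid Decay rates (1/us), strictly increasing.
#' @param weights Non-negative intensity weights, same length; they are
#'   renormalized to sum to 1.
#' @return An object of class `size_distribution`.
#' @export
size_distribution <- function(gamma_grid, weights) {
  stopifnot(is.numeric(gamma_grid), is.numeric(weights),
            length(gamma_grid) == length(weights))
  if (any(!is.finite(gamma_grid)) || any(gamma_grid <= 0))
    stop("'gamma_grid' must be positive and finite")
  if (length(gamma_grid) > 1L && any(diff(gamma_grid) <= 0))
    stop("'gamma_grid' must be strictly increasing")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("'weights' must be non-negative and finite")
  s <- sum(weights)
  if (s <= 0) stop("'weights' must not be all zero")
  structure(list(gamma_grid = gamma_grid, weights = weights / s),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("Size distribution: %d grid points, Gamma in [%.3g, %.3g] 1/us\n",
              length(x$gamma_grid), min(x$gamma_grid), max(x$gamma_grid)))
  cat(sprintf("  mean Gamma = %.4g 1/us, %d mode(s)\n",
              sum(x$gamma_grid * x$weights), n_modes(x)))
  invisible(x)
}

#' @export
plot.size_distribution <- function(x, cfg = NULL, ...) {
  if (is.null(cfg)) {
    graphics::plot(x$gamma_grid, x$weights, type = "h", log = "x",
                   xlab = "Gamma (1/us)", ylab = "G(Gamma)", ...)
  } else {
    d <- stokes_einstein_diameter(x$gamma_grid, cfg)
    graphics::plot(d, x$weights, type = "h", log = "x",
                   xlab = "D_h (nm)", ylab = "G(D)", ...)
  }
}

# number of local maxima of the weight vector carrying at least a
# fraction eps of the tallest peak (eps suppresses numerical wiggles)
n_modes <- function(dist, eps = 0.01) {
  w <- dist$weights
  thr <- eps * max(w)
  n <- length(w)
  if (n < 2L) return(as.integer(w[1] > thr))
  up <- c(TRUE, diff(w) > 0)
  down <- c(diff(w) < 0, TRUE)
  sum(up & down & w > thr)
}

.second_diff_matrix <- function(n) {
  if (n < 3L) return(matrix(0, 0, n))
  D <- matrix(0, n - 2L, n)
  for (i in seq_len(n - 2L)) D[i, i + 0:2] <- c(1, -2, 1)
  D
}

# one regularized NNLS solve; returns weights and the two L-curve norms
.contin_solve <- function(A, y, D, lambda) {
  Aa <- rbind(A, sqrt(lambda) * D)
  ya <- c(y, rep(0, nrow(D)))
  sol <- pracma::lsqnonneg(Aa, ya)
  w <- sol$x
  list(w = w,
       rnorm = sqrt(sum((y - A %*% w)^2)),
       snorm = sqrt(sum((D %*% w)^2)))
}

#' CONTIN-like inversion of a correlogram
#'
#' Recovers the intensity-weighted decay-rate distribution by regularized
#' non-negative least squares on the field correlation function (the
#' square root of the baseline-subtracted, amplitude-normalized g2).
#'
#' @param c A [correlogram()].
#' @param grid_size Number of log-spaced grid points (default 80) spanning
#'   `[0.1 / t_max, 10 / t_min]`.
#' @param reg_lambda Smoothness penalty weight (squared second differences
#'   of the weights), a positive number, or `"auto"` to pick the L-curve
#'   corner on a 20-point log-spaced lambda grid.
#' @param gamma_range Optional length-2 numeric overriding the default
#'   grid span (1/us).
#' @param baseline Optional known baseline B. By default B is estimated
#'   from the mean of the last 5% of lags and refined by minimizing the
#'   g2-domain reconstruction residual; the amplitude beta is then the
#'   initial decay above B (its scale cancels in the normalized weights).
#' @return An object of classes `contin_fit` and `size_distribution`,
#'   with additional elements `reg_lambda` (the value used; for
#'   `"auto"` the selected corner), `baseline`, `amplitude`, `residual_norm`
#'   and `correlogram`.
#' @examples
#' dist <- size_distribution(0.0024, 1)
#' cor <- simulate_correlogram(dist, noise_sd = 0, seed = 1)
#' inv <- invert_contin(cor, reg_lambda = 1e-8)
#' @export
invert_contin <- function(c, grid_size = 80, reg_lambda = "auto",
                          gamma_range = NULL, baseline = NULL) {
  stopifnot(inherits(c, "correlogram"))
  grid_size <- as.integer(grid_size)
  if (grid_size < 4L) stop("'grid_size' must be at least 4")
  auto <- identical(reg_lambda, "auto")
  if (!auto && (!is.numeric(reg_lambda) || reg_lambda < 0))
    stop("'reg_lambda' must be a non-negative number or \"auto\"")

  t <- c$lag_us
  g2 <- c$g2
  if (is.null(gamma_range))
    gamma_range <- c(0.1 / max(t), 10 / min(t))
  grid <- exp(seq(log(gamma_range[1]), log(gamma_range[2]),
                  length.out = grid_size))
  A <- exp(-outer(t, grid))
  D <- .second_diff_matrix(grid_size)

  if (is.null(baseline)) {
    ktail <- max(3L, ceiling(0.05 * length(g2)))
    b0 <- mean(g2[(length(g2) - ktail + 1L):length(g2)])
    amp0 <- max(g2) - b0
    if (amp0 <= 0) stop("no decay above the estimated baseline")
    lam_ref <- if (auto) 1e-6 else max(reg_lambda, 1e-10)
    # components with Gamma < 1/t_max barely decay over the window and
    # are degenerate with the baseline; exclude them while refining B
    dec <- grid >= 1 / max(t)
    A_ref <- A[, dec, drop = FALSE]
    D_ref <- .second_diff_matrix(sum(dec))
    obj <- function(B) {
      bet <- max(max(g2) - B, 1e-12)
      yb <- sqrt(pmax(g2 - B, 0) / bet)
      w <- .contin_solve(A_ref, yb, D_ref, lam_ref)$w
      sum((g2 - (B + bet * as.numeric(A_ref %*% w)^2))^2)
    }
    # the objective can be mildly non-unimodal under noise: coarse grid
    # scan first, then local golden-section refinement around the best cell
    bgrid <- seq(b0 - 0.05 * amp0, b0 + 0.05 * amp0, length.out = 26)
    vals <- vapply(bgrid, obj, 0)
    i <- which.min(vals)
    lohi <- bgrid[c(max(i - 1L, 1L), min(i + 1L, length(bgrid)))]
    B <- stats::optimize(obj, interval = lohi, tol = 1e-7)$minimum
    if (obj(B) > vals[i]) B <- bgrid[i]
  } else B <- baseline
  beta <- max(g2) - B
  if (beta <= 0) stop("baseline leaves no decay amplitude")
  if (beta < 0.05)
    warning("low intercept (beta < 0.05): inversion may be unreliable")
  y <- sqrt(pmax(g2 - B, 0) / beta)

  if (auto) {
    lgrid <- 10^seq(-6, 2, length.out = 20)
    sols <- lapply(lgrid, function(l) .contin_solve(A, y, D, l))
    lr <- log(pmax(vapply(sols, `[[`, 0, "rnorm"), 1e-15))
    ls <- log(pmax(vapply(sols, `[[`, 0, "snorm"), 1e-15))
    # discrete curvature of the L-curve (log residual vs log seminorm)
    k <- length(lgrid)
    curv <- rep(-Inf, k)
    for (i in 2:(k - 1L)) {
      x1 <- lr[i] - lr[i - 1]; y1 <- ls[i] - ls[i - 1]
      x2 <- lr[i + 1] - lr[i]; y2 <- ls[i + 1] - ls[i]
      cross <- x1 * y2 - y1 * x2
      den <- sqrt((x1^2 + y1^2) * (x2^2 + y2^2) *
                    ((x1 + x2)^2 + (y1 + y2)^2))
      if (den > 0) curv[i] <- cross / den
    }
    best <- which.max(curv)
    lambda <- lgrid[best]
    sol <- sols[[best]]
  } else {
    lambda <- reg_lambda
    sol <- .contin_solve(A, y, D, lambda)
  }

  if (all(sol$w <= 0))
    stop("inversion returned the all-zero solution; ",
         "check baseline estimation or decrease reg_lambda")

  out <- size_distribution(grid, sol$w)
  out$reg_lambda <- lambda
  out$auto_lambda <- auto
  out$baseline <- B
  out$amplitude <- beta
  out$residual_norm <- sol$rnorm
  out$correlogram <- c
  class(out) <- c("contin_fit", class(out))
  out
}

#' @export
print.contin_fit <- function(x, ...) {
  cat("CONTIN-like inversion\n")
  cat(sprintf("  grid: %d points, Gamma in [%.3g, %.3g] 1/us\n",
              length(x$gamma_grid), min(x$gamma_grid), max(x$gamma_grid)))
  cat(sprintf("  reg_lambda = %.3g%s\n", x$reg_lambda,
              if (isTRUE(x$auto_lambda)) " (L-curve corner)" else ""))
  cat(sprintf("  baseline = %.6g, amplitude = %.4g, residual norm = %.3g\n",
              x$baseline, x$amplitude, x$residual_norm))
  cat(sprintf("  %d mode(s); mean Gamma = %.4g 1/us\n",
              n_modes(x), sum(x$gamma_grid * x$weights)))
  invisible(x)
}

#' Harmonic-mean hydrodynamic diameter of a size distribution
#'
#' Maps the decay-rate grid to diameters by the Stokes-Einstein relation
#' and returns the intensity-weighted harmonic mean
#' `1 / sum_i(G_i / D_i)`, the size average that the mean decay rate of a
#' polydisperse correlogram actually estimates.
#'
#' @param dist A [size_distribution()] (weights must be normalized and
#'   non-negative, as the constructor guarantees).
#' @param cfg An [optical_config()].
#' @return Harmonic-mean diameter (nm).
#' @examples
#' d <- size_distribution(gamma_from_diameter(c(50, 100), optical_config()),
#'                        c(0.5, 0.5))
#' harmonic_mean_diameter(d, optical_config())  # 66.67 nm
#' @export
harmonic_mean_diameter <- function(dist, cfg) {
  stopifnot(inherits(dist, "size_distribution"),
            inherits(cfg, "optical_config"))
  w <- dist$weights
  if (any(w < 0)) stop("weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) stop("weights must be normalized to sum 1")
  d <- stokes_einstein_diameter(dist$gamma_grid, cfg)
  1 / sum(w / d)
}
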