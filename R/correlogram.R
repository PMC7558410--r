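# Correlogram container: the measured intensity autocorrelation function
# g2(t) on a grid of lag times.

#' Intensity autocorrelation record
#'
#' @param lag_us Lag times (us), strictly increasing, at least 10 points.
#' @param g2 Measured normalized intensity autocorrelation values, same
#'   length as `lag_us`, all finite.
#' @return A data frame of class `correlogram` with columns `lag_us`, `g2`.
#' @export
correlogram <- function(lag_us, g2) {
  if (!is.numeric(lag_us) || !is.numeric(g2))
    stop("'lag_us' and 'g2' must be numeric")
  if (length(lag_us) != length(g2))
    stop("'lag_us' and 'g2' must have equal length")
  if (length(lag_us) < 10L)
    stop("a correlogram needs at least 10 points")
  if (any(!is.finite(lag_us)) || any(!is.finite(g2)))
    stop("lags and g2 values must be finite")
  if (any(lag_us <= 0))
    stop("lag times must be positive")
  if (any(diff(lag_us) <= 0))
    stop("lag times must be strictly increasing")
  structure(data.frame(lag_us = lag_us, g2 = g2),
            class = c("correlogram", "data.frame"))
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("Correlogram: %d lags, t in [%.3g, %.3g] us, g2 in [%.4g, %.4g]\n",
              nrow(x), min(x$lag_us), max(x$lag_us), min(x$g2), max(x$g2)))
  invisible(x)
}

#' @export
plot.correlogram <- function(x, ...) {
  graphics::plot(x$lag_us, x$g2, log = "x",
                 xlab = "lag time (us)", ylab = "g2(t)", ...)
}

# Baseline estimate: mean of g2 over the last 10% of lags (at least 3 pts).
.estimate_baseline <- function(c) {
  n <- nrow(c)
  k <- max(3L, ceiling(0.1 * n))
  mean(c$g2[(n - k + 1L):n])
}
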