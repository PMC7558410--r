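# Elastic (Rayleigh) peak integration of spectrofluorimeter emission
# spectra. With excitation and emission wavelengths set equal, the band
# centered at the excitation wavelength is elastically scattered light;
# its background-subtracted area is proportional to the static scattered
# intensity and can replace goniometer readings in the intensity ratio.

#' Spectrofluorimeter emission spectrum
#'
#' @param wavelength_nm Emission wavelength grid (nm), strictly
#'   increasing.
#' @param intensity Detector counts (arbitrary units), finite, same
#'   length.
#' @param excitation_nm Excitation wavelength (nm).
#' @return A data frame of class `emission_spectrum` with attribute
#'   `excitation_nm`.
#' @export
emission_spectrum <- function(wavelength_nm, intensity, excitation_nm) {
  if (!is.numeric(wavelength_nm) || !is.numeric(intensity))
    stop("'wavelength_nm' and 'intensity' must be numeric")
  if (length(wavelength_nm) != length(intensity))
    stop("grid and intensity lengths differ")
  if (any(!is.finite(wavelength_nm)) || any(!is.finite(intensity)))
    stop("wavelengths and intensities must be finite")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (!is.numeric(excitation_nm) || !is.finite(excitation_nm) ||
      excitation_nm <= 0)
    stop("'excitation_nm' must be a positive number")
  structure(data.frame(wavelength_nm = wavelength_nm,
                       intensity = intensity),
            excitation_nm = excitation_nm,
            class = c("emission_spectrum", "data.frame"))
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf(
    "Emission spectrum: %d points, %.4g-%.4g nm, excitation %.4g nm\n",
    nrow(x), min(x$wavelength_nm), max(x$wavelength_nm),
    attr(x, "excitation_nm")))
  invisible(x)
}

#' @export
plot.emission_spectrum <- function(x, ...) {
  graphics::plot(x$wavelength_nm, x$intensity, type = "l",
                 xlab = "emission wavelength (nm)",
                 ylab = "intensity (a.u.)", ...)
  graphics::abline(v = attr(x, "excitation_nm"), lty = 2)
}

#' Area under the elastic peak
#'
#' Background-subtracted trapezoidal integral of the emission intensity
#' over a window centered at the excitation wavelength. The default
#' background model fits a straight baseline to the two flanking bands
#' just outside the window (each one window half-width wide), which makes
#' the area invariant to any constant offset. Alternatively an explicit
#' buffer spectrum on the same grid can be subtracted.
#'
#' @param spec An [emission_spectrum()].
#' @param window_nm Window half-width (nm); default 5. The integration
#'   interval is excitation +/- `window_nm`.
#' @param background Either `"flanking"` (default) or an
#'   [emission_spectrum()] on the same wavelength grid to subtract.
#' @return Background-subtracted area (a.u. nm), clipped at 0 (with a
#'   warning) if the net area is negative.
#' @examples
#' sp <- simulate_emission_spectrum(100, noise_sd = 0, seed = 1)
#' integrate_elastic_peak(sp)
#' @export
integrate_elastic_peak <- function(spec, window_nm = 5,
                                   background = "flanking") {
  stopifnot(inherits(spec, "emission_spectrum"))
  if (!is.numeric(window_nm) || window_nm <= 0)
    stop("'window_nm' must be positive")
  lam <- spec$wavelength_nm
  y <- spec$intensity
  ex <- attr(spec, "excitation_nm")
  lo <- ex - window_nm; hi <- ex + window_nm
  if (lo < min(lam) || hi > max(lam))
    stop(sprintf("integration window [%.4g, %.4g] nm exceeds the spectrum (%.4g-%.4g nm)",
                 lo, hi, min(lam), max(lam)))

  if (inherits(background, "emission_spectrum")) {
    if (nrow(background) != length(lam) ||
        any(abs(background$wavelength_nm - lam) > 1e-9))
      stop("background spectrum must share the sample's wavelength grid")
    y <- y - background$intensity
    base <- rep(0, length(lam))
  } else if (identical(background, "flanking")) {
    fl <- (lam >= lo - window_nm & lam < lo) |
          (lam > hi & lam <= hi + window_nm)
    if (sum(fl) < 2L)
      stop("too few points in the flanking bands to fit a baseline")
    bl <- stats::lm(y[fl] ~ lam[fl])
    base <- stats::coef(bl)[[1]] + stats::coef(bl)[[2]] * lam
  } else stop("'background' must be \"flanking\" or an emission_spectrum")

  inside <- lam >= lo & lam <= hi
  if (sum(inside) < 2L) stop("fewer than 2 points inside the window")
  area <- pracma::trapz(lam[inside], (y - base)[inside])
  if (area < 0) {
    # warn only when the deficit exceeds roundoff on the integrand scale
    if (area < -1e-9 * max(abs(y), 1) * 2 * window_nm)
      warning(sprintf("negative net peak area (%.3g); clipped to 0", area))
    area <- 0
  }
  area
}

#' Intensity ratio from two elastic-peak areas
#'
#' Uses the two background-subtracted elastic-peak areas as the intensity
#' measures in the dilution-corrected ratio gamma = (A1 d1)/(A2 d2);
#' instrument settings (PMT voltage, slits) cancel as long as the two
#' spectra were acquired identically.
#'
#' @param a1,a2 Elastic-peak areas of the extrusion-I and -II samples.
#' @param d1,d2 Dilution factors.
#' @return The dimensionless ratio gamma; see [compute_gamma()].
#' @examples
#' peak_areas_to_gamma(200, 50, 250, 5)  # 8
#' @export
peak_areas_to_gamma <- function(a1, d1, a2, d2) {
  compute_gamma(a1, d1, a2, d2)
}
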