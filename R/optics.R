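# Optical geometry, Stokes-Einstein conversion and the thin-shell vesicle
# mass model.
#
# Unit conventions, fixed package-wide:
#   wavelength nm (in vacuo), angle degrees, temperature K, viscosity mPa s,
#   decay rate Gamma in 1/us, scattering vector q in 1/um, diameter nm,
#   concentration mg/mL, volume mL, mass mg.

.kB <- 1.380649e-23  # Boltzmann constant, J/K (exact, SI)

#' Optical configuration of a light-scattering experiment
#'
#' Bundles the instrument geometry and solvent properties needed to convert
#' measured decay rates into hydrodynamic sizes. Defaults describe a green
#' (532 nm) laser at 90 degrees in water thermostated at 20 degrees C.
#'
#' @param wavelength_nm Laser wavelength in vacuo (nm).
#' @param angle_deg Scattering angle (degrees), strictly between 0 and 180.
#' @param refractive_index Solvent refractive index (>= 1); 1.333 for water.
#' @param temperature_K Absolute temperature (K).
#' @param viscosity_mPas Solvent dynamic viscosity (mPa s); 1.002 for water
#'   at 20 degrees C.
#'
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config()
#' scattering_vector(cfg)  # about 22.3 1/um
#' @export
optical_config <- function(wavelength_nm = 532, angle_deg = 90,
                           refractive_index = 1.333,
                           temperature_K = 293.15, viscosity_mPas = 1.002) {
  stopifnot(is.numeric(wavelength_nm), length(wavelength_nm) == 1L,
            is.numeric(angle_deg), length(angle_deg) == 1L,
            is.numeric(refractive_index), is.numeric(temperature_K),
            is.numeric(viscosity_mPas))
  if (!is.finite(wavelength_nm) || wavelength_nm <= 0)
    stop("'wavelength_nm' must be a positive finite number")
  if (!is.finite(angle_deg) || angle_deg <= 0 || angle_deg >= 180)
    stop("'angle_deg' must lie strictly between 0 and 180 degrees")
  if (!is.finite(refractive_index) || refractive_index < 1)
    stop("'refractive_index' must be >= 1")
  if (!is.finite(temperature_K) || temperature_K <= 0)
    stop("'temperature_K' must be positive")
  if (!is.finite(viscosity_mPas) || viscosity_mPas <= 0)
    stop("'viscosity_mPas' must be positive")
  structure(list(wavelength_nm = wavelength_nm, angle_deg = angle_deg,
                 refractive_index = refractive_index,
                 temperature_K = temperature_K,
                 viscosity_mPas = viscosity_mPas),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("Optical configuration\n")
  cat(sprintf("  wavelength      : %g nm\n", x$wavelength_nm))
  cat(sprintf("  scattering angle: %g deg\n", x$angle_deg))
  cat(sprintf("  refractive index: %g\n", x$refractive_index))
  cat(sprintf("  temperature     : %g K\n", x$temperature_K))
  cat(sprintf("  viscosity       : %g mPa s\n", x$viscosity_mPas))
  cat(sprintf("  q               : %.4g 1/um\n", scattering_vector(x)))
  invisible(x)
}

#' Scattering vector magnitude
#'
#' Computes q = (4 pi n0 / lambda) sin(theta / 2) in reciprocal micrometers.
#' The solvent refractive index enters because the relevant wavelength is
#' the one in the medium, the standard light-scattering convention.
#'
#' @param cfg An [optical_config()].
#' @return Scattering vector magnitude (1/um).
#' @examples
#' scattering_vector(optical_config(532, 90, 1.333))
#' @export
scattering_vector <- function(cfg) {
  stopifnot(inherits(cfg, "optical_config"))
  lambda_um <- cfg$wavelength_nm / 1000
  4 * pi * cfg$refractive_index / lambda_um * sin(cfg$angle_deg * pi / 360)
}

#' Hydrodynamic diameter from a mean decay rate
#'
#' Applies the Stokes-Einstein relation D_h = kB T q^2 / (3 pi eta Gamma)
#' to convert the mean decay rate of the intensity autocorrelation function
#' into an intensity-weighted average hydrodynamic diameter.
#'
#' @param gamma_bar Mean decay rate (1/us), positive.
#' @param cfg An [optical_config()] supplying temperature and viscosity.
#' @param q Scattering vector (1/um); defaults to [scattering_vector()] of
#'   `cfg`, overridable so that a rounded printed value can be used as-is.
#' @return Hydrodynamic diameter (nm).
#' @seealso [gamma_from_diameter()] for the exact inverse.
#' @examples
#' stokes_einstein_diameter(0.00240, optical_config())
#' @export
stokes_einstein_diameter <- function(gamma_bar, cfg, q = scattering_vector(cfg)) {
  stopifnot(inherits(cfg, "optical_config"), is.numeric(gamma_bar))
  if (any(!is.finite(gamma_bar)) || any(gamma_bar <= 0))
    stop("'gamma_bar' must be positive and finite")
  if (any(!is.finite(q)) || any(q <= 0)) stop("'q' must be positive")
  q_m <- q * 1e6            # 1/m
  gamma_s <- gamma_bar * 1e6  # 1/s
  eta <- cfg$viscosity_mPas * 1e-3  # Pa s
  d_m <- .kB * cfg$temperature_K * q_m^2 / (3 * pi * eta * gamma_s)
  d_m * 1e9
}

#' Mean decay rate for a given hydrodynamic diameter
#'
#' Exact algebraic inverse of [stokes_einstein_diameter()].
#'
#' @inheritParams stokes_einstein_diameter
#' @param diameter_nm Hydrodynamic diameter (nm), positive.
#' @return Decay rate (1/us).
#' @export
gamma_from_diameter <- function(diameter_nm, cfg, q = scattering_vector(cfg)) {
  stopifnot(inherits(cfg, "optical_config"), is.numeric(diameter_nm))
  if (any(!is.finite(diameter_nm)) || any(diameter_nm <= 0))
    stop("'diameter_nm' must be positive and finite")
  q_m <- q * 1e6
  eta <- cfg$viscosity_mPas * 1e-3
  gamma_s <- .kB * cfg$temperature_K * q_m^2 /
    (3 * pi * eta * (diameter_nm * 1e-9))
  gamma_s / 1e6
}

#' Thin-shell vesicle mass model
#'
#' A unilamellar vesicle is modeled as a sphere with all lipid mass in an
#' infinitely thin shell of diameter D, so its mass scales as D^2:
#' M(D) = (2 pi M_lip / A_lip) D^2, where M_lip is the mass of one lipid
#' molecule and A_lip the average area per lipid head group.
#'
#' @param lipid_mass_Da Mass of one lipid molecule (Da); default 760.1,
#'   the molar mass of POPC.
#' @param head_area_nm2 Average area per lipid head group (nm^2); default
#'   0.63, the accepted value for POPC.
#' @return An object of class `shell_model`.
#' @export
shell_model <- function(lipid_mass_Da = 760.1, head_area_nm2 = 0.63) {
  if (!is.numeric(lipid_mass_Da) || !is.finite(lipid_mass_Da) ||
      lipid_mass_Da <= 0)
    stop("'lipid_mass_Da' must be positive")
  if (!is.numeric(head_area_nm2) || !is.finite(head_area_nm2) ||
      head_area_nm2 <= 0)
    stop("'head_area_nm2' must be positive")
  structure(list(lipid_mass_Da = lipid_mass_Da,
                 head_area_nm2 = head_area_nm2),
            class = "shell_model")
}

#' @export
print.shell_model <- function(x, ...) {
  cat("Thin-shell vesicle mass model\n")
  cat(sprintf("  lipid mass     : %g Da\n", x$lipid_mass_Da))
  cat(sprintf("  head-group area: %g nm^2\n", x$head_area_nm2))
  cat(sprintf("  M(100 nm)      : %.4g MDa\n",
              shell_mass(100, x) / 1e6))
  invisible(x)
}

#' Mass of a thin-shell vesicle
#'
#' @param diameter_nm Vesicle diameter (nm), positive; vectorized.
#' @param model A [shell_model()].
#' @return Vesicle mass (Da). The mass counts both leaflets through the
#'   factor 2 pi / A_lip (area of both leaflet surfaces per head group).
#' @examples
#' shell_mass(100) / shell_mass(50)  # exactly 4
#' @export
shell_mass <- function(diameter_nm, model = shell_model()) {
  stopifnot(inherits(model, "shell_model"), is.numeric(diameter_nm))
  if (any(!is.finite(diameter_nm)) || any(diameter_nm <= 0))
    stop("'diameter_nm' must be positive and finite")
  2 * pi * model$lipid_mass_Da / model$head_area_nm2 * diameter_nm^2
}

#' Detection-limit scaling with vesicle size
#'
#' Under the thin-shell model the scattered intensity per unit weight
#' concentration grows as the vesicle mass, I = k Mw C with Mw
#' proportional to D^2, so the minimum detectable concentration at a fixed
#' intensity threshold falls as 1/D^2. Given a reference limit at a
#' reference diameter, returns the limit at another diameter.
#'
#' @param c_lim_ref Reference concentration limit (mg/mL) at `d_ref_nm`.
#' @param d_ref_nm Reference diameter (nm).
#' @param d_nm Query diameter (nm); vectorized.
#' @return Concentration limit at `d_nm` (mg/mL).
#' @examples
#' detection_limit(0.01, 50, c(100, 200))  # 4x and 16x smaller
#' @export
detection_limit <- function(c_lim_ref, d_ref_nm, d_nm) {
  vals <- c(c_lim_ref, d_ref_nm, d_nm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all arguments must be positive and finite")
  c_lim_ref * (d_ref_nm / d_nm)^2
}
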