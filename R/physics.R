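#' Mayneord effective atomic number
#'
#' Power-law effective atomic number of a mixture,
#' \deqn{Z_{eff} = \left[\frac{\sum_i w_i (Z_i/A_i) Z_i^{n}}{\sum_i w_i (Z_i/A_i)}\right]^{1/n}}
#' with exponent `n = 3.21`. For a single-element composition this reduces to
#' that element's atomic number; in general the result lies between the
#' smallest and largest Z in the mixture.
#'
#' @param composition A [composition()] object.
#' @param n Mayneord exponent (default 3.21).
#' @return Dimensionless effective atomic number.
#' @examples
#' mayneord_zeff(composition(c("H", "O"), c(0.1119, 0.8881)))
#' @export
mayneord_zeff <- function(composition, n = physics_constants()$mayneord_n) {
  stopifnot(inherits(composition, "composition"))
  w <- composition$w; Z <- composition$Z; A <- composition$A
  if (sum(w) <= 0) stop("all-zero weights", call. = FALSE)
  lambda <- w * Z / A
  (sum(lambda * Z^n) / sum(lambda))^(1 / n)
}

#' Theoretical relative electron density
#'
#' Electron density of a material relative to water,
#' \deqn{\rho_e = \frac{\rho N_A \sum_i w_i Z_i/A_i}{\rho_{e,w}},}
#' strictly linear in the mass density.
#'
#' @param composition A [composition()] object.
#' @param mass_density Mass density in g/cm3 (> 0).
#' @param constants Constants list from [physics_constants()].
#' @return Dimensionless RED.
#' @examples
#' relative_electron_density(composition(c("H", "O"), c(0.1119, 0.8881)), 1.0)
#' @export
relative_electron_density <- function(composition, mass_density,
                                      constants = physics_constants()) {
  stopifnot(inherits(composition, "composition"))
  if (!is.numeric(mass_density) || length(mass_density) != 1L ||
      !is.finite(mass_density) || mass_density <= 0)
    stop("mass_density must be a single positive number", call. = FALSE)
  za <- sum(composition$w * composition$Z / composition$A)
  mass_density * constants$avogadro * za / constants$rho_e_water
}

#' Bragg-additivity mean excitation energy
#'
#' Electron-weighted logarithmic mean of the elemental mean excitation
#' energies,
#' \deqn{\ln I_m = \frac{\sum_j w_j (Z_j/A_j) \ln I_j}{\sum_j w_j (Z_j/A_j)}.}
#'
#' @param composition A [composition()] object whose every component carries an
#'   elemental `I_eV`.
#' @return `ln I` in ln(eV). Use `exp()` for the I-value itself.
#' @examples
#' exp(bragg_additivity_lnI(composition(c("H", "O"), c(0.1119, 0.8881)))) # 75.3
#' @export
bragg_additivity_lnI <- function(composition) {
  stopifnot(inherits(composition, "composition"))
  I <- composition$I_eV
  if (any(is.na(I)) || any(I <= 0))
    stop("every component needs a positive elemental mean excitation energy",
         call. = FALSE)
  lambda <- composition$w * composition$Z / composition$A
  sum(lambda * log(I)) / sum(lambda)
}

# beta^2 from proton kinetic energy via relativistic kinematics
beta2_from_energy <- function(kinetic_energy_mev,
                              proton_rest_mev = physics_constants()$proton_rest_mev) {
  stopifnot(all(kinetic_energy_mev > 0))
  1 - (proton_rest_mev / (kinetic_energy_mev + proton_rest_mev))^2
}

#' Bethe-Bloch relative stopping power
#'
#' Proton stopping power of a material relative to water,
#' \deqn{RSP = \rho_{e,rel} \cdot
#'   \frac{\ln\!\frac{2 m_e c^2 \beta^2}{1-\beta^2} - \beta^2 - \ln I_m}
#'        {\ln\!\frac{2 m_e c^2 \beta^2}{1-\beta^2} - \beta^2 - \ln I_w},}
#' with \eqn{I_w = 75.3} eV and \eqn{\beta} from the proton kinetic energy via
#' relativistic kinematics. When `I_m == I_w` the bracket ratio is exactly 1
#' and the RSP equals the RED. The result is insensitive to the choice of
#' kinetic energy (< 1% over 80--200 MeV for physiological I-values).
#'
#' @param red Relative electron density (> 0); vectorized.
#' @param I_m Material mean excitation energy in eV (> 0); vectorized.
#' @param kinetic_energy Proton kinetic energy in MeV, in `[1, 300]`.
#' @param constants Constants list from [physics_constants()].
#' @return Dimensionless RSP, same length as `red`/`I_m`.
#' @examples
#' bethe_bloch_rsp(1.0, 75.3, 100) # exactly 1
#' @export
bethe_bloch_rsp <- function(red, I_m, kinetic_energy = NULL,
                            constants = physics_constants()) {
  if (is.null(kinetic_energy)) kinetic_energy <- constants$kinetic_energy_mev
  stopifnot(is.numeric(kinetic_energy), length(kinetic_energy) == 1L,
            kinetic_energy >= 1, kinetic_energy <= 300)
  if (any(red <= 0, na.rm = TRUE)) stop("red must be > 0", call. = FALSE)
  if (any(I_m <= 0, na.rm = TRUE)) stop("I_m must be > 0", call. = FALSE)
  b2 <- beta2_from_energy(kinetic_energy, constants$proton_rest_mev)
  # 2 m_e c^2 in eV so that I in eV divides out inside the log
  core <- log(2 * constants$electron_rest_mev * 1e6 * b2 / (1 - b2)) - b2
  den <- core - log(constants$i_water_ev)
  num <- core - log(I_m)
  if (den <= 0 || any(num <= 0, na.rm = TRUE))
    stop("stopping-power bracket is non-positive (I too large for this energy)",
         call. = FALSE)
  red * num / den
}

#' RSP from a water-equivalent-thickness measurement
#'
#' Ratio of the measured water equivalent thickness of a slab to its physical
#' thickness, the definition used to turn multilayer-ionization-chamber range
#' measurements into reference RSP values.
#'
#' @param wet Water equivalent thickness (mm, >= 0).
#' @param thickness Physical thickness (mm, > 0).
#' @return Dimensionless RSP.
#' @examples
#' rsp_from_wet(30, 20) # 1.5
#' @export
rsp_from_wet <- function(wet, thickness) {
  if (any(!is.finite(thickness)) || any(thickness <= 0))
    stop("thickness must be > 0", call. = FALSE)
  if (any(wet < 0)) stop("wet must be >= 0", call. = FALSE)
  wet / thickness
}
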