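#' Physical constants used by the stopping-power physics
#'
#' Returns the fixed constants entering the Bethe-Bloch stopping-power ratio
#' and the reference-value formulas. The water mean excitation energy is fixed
#' at 75.3 eV; the water electron density is derived from the two-element water
#' composition so that water evaluates to a relative electron density of
#' exactly 1 at 1.000 g/cm3.
#'
#' @param kinetic_energy_mev Default proton kinetic energy in MeV used when a
#'   caller does not supply one. Must lie in `[1, 300]`.
#' @return A list with elements `electron_rest_mev` (0.511), `proton_rest_mev`
#'   (938.272), `i_water_ev` (75.3), `rho_e_water` (electrons/cm3),
#'   `avogadro`, `mayneord_n` (3.21) and `kinetic_energy_mev`.
#' @examples
#' physics_constants()$i_water_ev
#' @export
physics_constants <- function(kinetic_energy_mev = 100) {
  stopifnot(is.numeric(kinetic_energy_mev), length(kinetic_energy_mev) == 1L,
            kinetic_energy_mev >= 1, kinetic_energy_mev <= 300)
  avogadro <- 6.02214076e23
  # electrons/cm3 for water at 1.000 g/cm3, from w_H = 0.1119, w_O = 0.8881
  rho_e_water <- avogadro * (0.1119 * 1 / 1.008 + 0.8881 * 8 / 15.999)
  list(
    electron_rest_mev  = 0.511,
    proton_rest_mev    = 938.272,
    i_water_ev         = 75.3,
    rho_e_water        = rho_e_water,
    avogadro           = avogadro,
    mayneord_n         = 3.21,
    kinetic_energy_mev = kinetic_energy_mev
  )
}

#' Elemental data table
#'
#' The bundled element table: atomic number, standard atomic weight, and the
#' condensed-phase mean excitation energy used in stoichiometric calibration
#' work (with these I-values Bragg additivity on water yields 75.3 eV).
#'
#' @return A data frame with columns `symbol`, `Z`, `A_gmol`, `I_eV`, one row
#'   per supported element.
#' @export
element_data <- function() {
  path <- system.file("extdata", "elements.csv", package = "dectrsp",
                      mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
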