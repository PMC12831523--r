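#' Convert Zeff and RED volumes to an RSP volume
#'
#' Per voxel, the mean excitation energy is obtained from the Zeff map through
#' the empirical correlation and the Bethe-Bloch stopping-power ratio is
#' evaluated with that I-value and the voxel's RED. The output grid is
#' identical to the inputs. RED voxels that are non-positive (possible after
#' additive noise in near-air regions) are clamped to the air floor 0.001 and
#' their count reported via a message.
#'
#' @param zeff_vol,red_vol [property_volume()]s on identical grids with
#'   quantities `"zeff"` and `"red"`.
#' @param correlation A [zeff_I_correlation()]; defaults to
#'   [default_correlation()].
#' @param kinetic_energy Proton kinetic energy in MeV (default 100).
#' @param quiet Suppress the clamp-count message.
#' @return A [property_volume()] with `quantity = "rsp"`.
#' @examples
#' \donttest{
#' spec <- preset_phantom("george_head")
#' maps <- render_property_maps(build_label_volume(spec, n_slices = 1), spec)
#' rsp <- rsp_map(maps$zeff, maps$red)
#' }
#' @export
rsp_map <- function(zeff_vol, red_vol, correlation = default_correlation(),
                    kinetic_energy = 100, quiet = FALSE) {
  stopifnot(inherits(zeff_vol, "property_volume"),
            inherits(red_vol, "property_volume"),
            zeff_vol$quantity == "zeff", red_vol$quantity == "red")
  if (!same_grid(zeff_vol, red_vol))
    stop("zeff and red volumes are not on the same grid", call. = FALSE)
  red <- red_vol$values
  n_clamped <- sum(red <= 0)
  if (n_clamped > 0) {
    red[red <= 0] <- 0.001
    if (!quiet)
      message(sprintf("rsp_map: clamped %d non-positive RED voxel(s) to 0.001",
                      n_clamped))
  }
  constants <- physics_constants(kinetic_energy)
  b2 <- beta2_from_energy(kinetic_energy, constants$proton_rest_mev)
  core <- log(2 * constants$electron_rest_mev * 1e6 * b2 / (1 - b2)) - b2
  lnI <- lookup_lnI(correlation, as.numeric(zeff_vol$values))
  rsp <- red * (core - lnI) / (core - log(constants$i_water_ev))
  property_volume(array(rsp, dim = dim(red)), spacing = red_vol$spacing,
                  origin = red_vol$origin, quantity = "rsp")
}
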