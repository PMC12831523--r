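# run expr with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Noise model for synthetic scans
#'
#' Independent additive zero-mean Gaussian noise levels for the three map
#' quantities, matching a row of the bundled phantom/dose noise table (see
#' [noise_preset()]).
#'
#' @param sigma_zeff,sigma_red,sigma_rsp Noise standard deviations (>= 0).
#' @param seed Integer seed making a simulation reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_zeff, sigma_red, sigma_rsp = 0, seed = 1L) {
  s <- c(sigma_zeff, sigma_red, sigma_rsp)
  if (any(!is.finite(s)) || any(s < 0))
    stop("noise sigmas must be finite and >= 0", call. = FALSE)
  structure(list(sigma_zeff = sigma_zeff, sigma_red = sigma_red,
                 sigma_rsp = sigma_rsp, seed = as.integer(seed)),
            class = "noise_model")
}

#' Load the bundled phantom/dose noise table
#'
#' Central-ROI noise standard deviations of the Zeff, RED and RSP maps as a
#' function of phantom size and CTDIvol, with the measurement-circle diameter
#' used for each phantom.
#'
#' @return A data frame with columns `key`, `phantom`, `diameter_cm`,
#'   `ctdi_mgy`, `sigma_zeff`, `sigma_red`, `sigma_rsp`, `roi_diameter_cm`.
#' @export
load_noise_table <- function() {
  path <- system.file("extdata", "phantom_noise_levels.csv",
                      package = "dectrsp", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Resolve a noise preset key
#'
#' @param key A `<phantom>_<CTDIvol>` key of the bundled noise table, e.g.
#'   `"george_head_82.77"`.
#' @param seed Seed stored in the returned model.
#' @return A [noise_model()].
#' @examples
#' noise_preset("george_head_82.77")$sigma_rsp # 0.003
#' @export
noise_preset <- function(key, seed = 1L) {
  tab <- load_noise_table()
  i <- match(key, tab$key)
  if (is.na(i))
    stop("unknown noise preset key '", key, "'; available: ",
         paste(tab$key, collapse = ", "), call. = FALSE)
  noise_model(tab$sigma_zeff[i], tab$sigma_red[i], tab$sigma_rsp[i],
              seed = seed)
}

#' Add Gaussian noise to a property volume
#'
#' Adds independent zero-mean Gaussian noise of standard deviation `sigma` to
#' every voxel. `sigma = 0` returns the input unchanged; the same seed yields
#' bit-identical output. Grid shape, spacing and quantity are never altered.
#'
#' @param vol A [property_volume()].
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return A [property_volume()] on the same grid.
#' @export
add_noise <- function(vol, sigma, seed = 1L) {
  stopifnot(inherits(vol, "property_volume"))
  if (!is.finite(sigma) || sigma < 0)
    stop("sigma must be finite and >= 0", call. = FALSE)
  if (sigma == 0) return(vol)
  noisy <- with_local_seed(seed, {
    vol$values + array(stats::rnorm(length(vol$values), 0, sigma),
                       dim = dim(vol$values))
  })
  property_volume(noisy, spacing = vol$spacing, origin = vol$origin,
                  quantity = vol$quantity)
}

#' Add exponential high-density proximity bias
#'
#' Models scatter/beam-hardening contamination near high-density structures as
#' an additive in-plane field `amplitude * exp(-d / decay)` per source, where
#' `d` is the in-plane distance (cm) from the source center. With zero
#' amplitude (the default study condition) this is the identity.
#'
#' @param vol A [property_volume()].
#' @param sources Data frame with columns `x`, `y` (cm), `amplitude`,
#'   `decay_cm` (> 0); may have zero rows.
#' @return A [property_volume()] on the same grid.
#' @export
add_highz_bias <- function(vol, sources) {
  stopifnot(inherits(vol, "property_volume"))
  if (is.null(sources) || nrow(sources) == 0L) return(vol)
  stopifnot(all(c("x", "y", "amplitude", "decay_cm") %in% names(sources)),
            all(sources$decay_cm > 0))
  co <- voxel_coords(vol)
  nx <- length(co$x); ny <- length(co$y)
  X <- matrix(co$x, nx, ny) / 10; Y <- matrix(co$y, nx, ny, byrow = TRUE) / 10
  field <- matrix(0, nx, ny)
  for (i in seq_len(nrow(sources)))
    field <- field + sources$amplitude[i] *
      exp(-sqrt((X - sources$x[i])^2 + (Y - sources$y[i])^2) /
            sources$decay_cm[i])
  vals <- vol$values + array(field, dim = dim(vol$values))
  property_volume(vals, spacing = vol$spacing, origin = vol$origin,
                  quantity = vol$quantity)
}
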