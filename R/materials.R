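#' Elemental composition of a material
#'
#' Builds a validated composition from element symbols and mass fractions.
#' Atomic number, atomic mass and elemental mean excitation energy are looked
#' up in [element_data()] unless supplied explicitly (useful for oracle tests).
#' Mass fractions are renormalized to sum to 1; if they deviate from 1 by more
#' than `1e-3` a warning reports the original sum.
#'
#' @param symbols Character vector of element symbols.
#' @param mass_fractions Numeric vector of mass fractions, same length,
#'   non-negative, not all zero.
#' @param Z,A,I_eV Optional numeric overrides of the element table (recycled
#'   against `symbols`).
#' @return An object of class `composition`: a data frame with columns
#'   `symbol`, `w`, `Z`, `A`, `I_eV`, with `sum(w) == 1`.
#' @examples
#' composition(c("H", "O"), c(0.1119, 0.8881))
#' @export
composition <- function(symbols, mass_fractions, Z = NULL, A = NULL,
                        I_eV = NULL) {
  if (length(symbols) == 0L)
    stop("composition must contain at least one element", call. = FALSE)
  if (length(symbols) != length(mass_fractions))
    stop("symbols and mass_fractions must have the same length", call. = FALSE)
  if (any(!is.finite(mass_fractions)) || any(mass_fractions < 0))
    stop("mass fractions must be finite and non-negative", call. = FALSE)
  total <- sum(mass_fractions)
  if (total <= 0)
    stop("mass fractions must not be all zero", call. = FALSE)
  if (abs(total - 1) > 1e-3)
    warning(sprintf("mass fractions sum to %.5f; renormalizing", total),
            call. = FALSE)
  tab <- element_data()
  idx <- match(symbols, tab$symbol)
  if (is.null(Z)) Z <- tab$Z[idx]
  if (is.null(A)) A <- tab$A_gmol[idx]
  if (is.null(I_eV)) I_eV <- tab$I_eV[idx]
  if (any(is.na(Z)) || any(is.na(A)))
    stop("unknown element symbol(s): ",
         paste(symbols[is.na(idx)], collapse = ", "), call. = FALSE)
  stopifnot(all(Z >= 1), all(A > 0))
  out <- data.frame(symbol = as.character(symbols), w = mass_fractions / total,
                    Z = as.numeric(Z), A = as.numeric(A),
                    I_eV = as.numeric(I_eV), stringsAsFactors = FALSE)
  class(out) <- c("composition", "data.frame")
  out
}

#' Material specification
#'
#' A named material: elemental composition plus mass density, with optional
#' manufacturer-supplied reference values. When a manufacturer-corrected RED
#' or Zeff is present it takes precedence as the ground-truth reference; the
#' composition-based values remain available for QA via [reference_table()].
#'
#' @param name Material name.
#' @param composition A [composition()] object.
#' @param mass_density Mass density in g/cm3 (> 0).
#' @param red_ref,zeff_ref Optional manufacturer reference RED / effective
#'   atomic number.
#' @param rsp_ref,rsp_ref_sd Optional measured reference RSP and its
#'   uncertainty.
#' @return An object of class `material_spec`.
#' @export
material_spec <- function(name, composition, mass_density,
                          red_ref = NA_real_, zeff_ref = NA_real_,
                          rsp_ref = NA_real_, rsp_ref_sd = NA_real_) {
  stopifnot(inherits(composition, "composition"),
            is.numeric(mass_density), length(mass_density) == 1L)
  if (!is.finite(mass_density) || mass_density <= 0)
    stop("mass_density must be > 0", call. = FALSE)
  for (v in c(red_ref, zeff_ref, rsp_ref))
    if (!is.na(v) && v <= 0)
      stop("reference overrides must be positive when present", call. = FALSE)
  structure(list(name = name, composition = composition,
                 mass_density = mass_density, red_ref = red_ref,
                 zeff_ref = zeff_ref, rsp_ref = rsp_ref,
                 rsp_ref_sd = rsp_ref_sd),
            class = "material_spec")
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("<material_spec> %s  (rho = %.3f g/cm3, %d elements)\n",
              x$name, x$mass_density, nrow(x$composition)))
  invisible(x)
}

#' Read a material table
#'
#' Parses the long-format delimited material table: composition rows carry
#' `(material, element, mass_fraction)`; one summary row per material (empty
#' `element`) carries `mass_density` and the optional reference columns
#' `red_ref`, `zeff_ref`, `rsp_ref`, `rsp_ref_sd`.
#'
#' @param path Path to the delimited file. Defaults to the bundled
#'   tissue-surrogate table.
#' @return A named list of [material_spec()] objects, in file order.
#' @examples
#' mats <- read_material_table()
#' names(mats)
#' @export
read_material_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "surrogate_materials.csv",
                        package = "dectrsp", mustWork = TRUE)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = c(material = "character",
                                        element = "character"))
  need <- c("material", "element", "mass_fraction", "mass_density")
  if (!all(need %in% names(raw)))
    stop("material table must contain columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  opt <- function(col, i) if (col %in% names(raw)) raw[[col]][i] else NA_real_
  out <- list()
  for (m in unique(raw$material)) {
    rows <- raw[raw$material == m, , drop = FALSE]
    comp_rows <- rows[nzchar(rows$element), , drop = FALSE]
    dens_rows <- rows[!nzchar(rows$element), , drop = FALSE]
    if (nrow(comp_rows) == 0L)
      stop(sprintf("material '%s' has no composition rows (first at file row %d)",
                   m, which(raw$material == m)[1]), call. = FALSE)
    if (nrow(dens_rows) != 1L || !is.finite(dens_rows$mass_density))
      stop(sprintf("material '%s' needs exactly one density row (rows %s)",
                   m, paste(which(raw$material == m), collapse = ",")),
           call. = FALSE)
    i <- as.integer(rownames(dens_rows))
    out[[m]] <- material_spec(
      name = m,
      composition = composition(comp_rows$element, comp_rows$mass_fraction),
      mass_density = dens_rows$mass_density,
      red_ref = opt("red_ref", i), zeff_ref = opt("zeff_ref", i),
      rsp_ref = opt("rsp_ref", i), rsp_ref_sd = opt("rsp_ref_sd", i))
  }
  out
}
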