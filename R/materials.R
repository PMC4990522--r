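#' Map hydroxyapatite content to a Hounsfield-unit value
#'
#' Affine calibration placing water (0 mg HA cm^-3) at 0 HU. The default
#' slope of 1.4 HU per (mg HA cm^-3) puts cortical bone
#' (800 mg HA cm^-3) at 1120 HU, above the 900 HU periosteal contouring
#' threshold, and the trabecular insert densities (<= 200 mg HA cm^-3)
#' below 500 HU, so a single threshold separates wall from insert.
#'
#' @param rho_ha hydroxyapatite content, mg HA cm^-3 (non-negative).
#' @param slope HU per (mg HA cm^-3); must be positive so the map is
#'   strictly increasing.
#' @return Hounsfield-unit value(s), same length as `rho_ha`.
#' @examples
#' hu_from_density(c(0, 50, 800))
#' @export
hu_from_density <- function(rho_ha, slope = 1.4) {
  if (!is.numeric(rho_ha) || any(!is.finite(rho_ha)))
    stop("'rho_ha' must be finite numeric")
  if (any(rho_ha < 0))
    stop("'rho_ha' must be non-negative (mg HA cm^-3)")
  if (!is.numeric(slope) || length(slope) != 1L || slope <= 0)
    stop("'slope' must be a single positive number")
  slope * rho_ha
}

#' Define a phantom material
#'
#' A material is described by its hydroxyapatite content `rho_ha`
#' (mg HA cm^-3), its relative electron density `rho_e` (water = 1) and
#' its linear attenuation coefficient `mu` (cm^-1) at the effective beam
#' energy. `rho_e` drives Compton scatter production; `mu` attenuates it.
#' When not given explicitly they default to simple water-anchored models:
#' `rho_e = 1 + 0.0005 * rho_ha` and `mu = 0.2 * rho_e` (water is about
#' 0.2 cm^-1 at effective CBCT energies).
#'
#' @param name material label.
#' @param rho_ha hydroxyapatite content, mg HA cm^-3 (>= 0).
#' @param rho_e relative electron density (> 0), or `NULL` to use the
#'   default model.
#' @param mu linear attenuation coefficient, cm^-1 (>= 0), or `NULL` to
#'   use the default model.
#' @param hu_slope slope passed to [hu_from_density()].
#' @param rho_e_slope electron density gained per (mg HA cm^-3) in the
#'   default model.
#' @return An object of class `material_spec` with fields `name`,
#'   `rho_ha`, `rho_e`, `mu` and `hu` (the image value of the material).
#' @examples
#' material_spec("trabecular", rho_ha = 50)
#' material_spec("dense water", rho_ha = 0, rho_e = 1.2)
#' @export
material_spec <- function(name, rho_ha = 0, rho_e = NULL, mu = NULL,
                          hu_slope = 1.4, rho_e_slope = 5e-4) {
  if (!is.numeric(rho_ha) || length(rho_ha) != 1L || !is.finite(rho_ha) ||
      rho_ha < 0)
    stop("'rho_ha' must be a single non-negative number")
  if (is.null(rho_e)) {
    rho_e <- 1 + rho_e_slope * rho_ha
  } else if (!is.numeric(rho_e) || length(rho_e) != 1L || rho_e < 0) {
    ## rho_e = 0 is the no-scatter limit; physical materials have rho_e > 0
    stop("'rho_e' must be a single non-negative number")
  }
  if (is.null(mu)) {
    mu <- 0.2 * rho_e
  } else if (!is.numeric(mu) || length(mu) != 1L || mu < 0) {
    stop("'mu' must be a single non-negative number")
  }
  structure(
    list(name = as.character(name), rho_ha = rho_ha, rho_e = rho_e,
         mu = mu, hu = hu_from_density(rho_ha, slope = hu_slope)),
    class = "material_spec")
}

#' Relative electron density of a material
#'
#' Returns the explicitly set electron density when the material carries
#' one; otherwise evaluates the default water-anchored model
#' `1 + 0.0005 * rho_ha`, which is monotone in hydroxyapatite content.
#'
#' @param material a [material_spec()] object.
#' @return relative electron density (water = 1).
#' @export
electron_density <- function(material) {
  stopifnot(inherits(material, "material_spec"))
  material$rho_e
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf(
    "<material_spec> %s: %g mg HA/cm^3, rho_e = %g, mu = %g /cm, %g HU\n",
    x$name, x$rho_ha, x$rho_e, x$mu, x$hu))
  invisible(x)
}
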