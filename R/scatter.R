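#' Total Compton scatter intensity of a homogeneous sphere
#'
#' Scatter production from Compton interactions is proportional to the
#' electron density of the scattering substance; photons scattered at
#' depth `r` are attenuated exponentially on their way out. The total
#' scatter intensity is
#' \deqn{I_s = \exp(-\mu r)\,\rho_e\,S,}
#' linear in the relative electron density `rho_e` and in the per-electron
#' scatter intensity `s`, and strictly decreasing in the optical depth
#' `mu * r`. The model is a proportionality: absolute units are arbitrary
#' and are fixed downstream by the streak gain.
#'
#' @param mu linear attenuation coefficient, cm^-1 (>= 0).
#' @param r radius (path length), cm (> 0).
#' @param rho_e relative electron density (>= 0).
#' @param s average scatter intensity per electron, arbitrary units (>= 0).
#' @return Scatter intensity, arbitrary units.
#' @examples
#' scatter_intensity(mu = 0.2, r = 1, rho_e = 2, s = 3)  # 6 * exp(-0.2)
#' @export
scatter_intensity <- function(mu, r, rho_e, s) {
  vals <- c(mu = mu, r = r, rho_e = rho_e, s = s)
  if (!is.numeric(vals) || length(vals) != 4L || any(!is.finite(vals)))
    stop("all arguments must be single finite numbers")
  if (any(vals < 0))
    stop("negative arguments are outside the model domain")
  if (r <= 0) stop("'r' must be positive (cm)")
  exp(-mu * r) * rho_e * s
}

#' Beam and detector geometry for the differential scatter model
#'
#' Houses the factors of the per-shell scatter model that the simulator
#' treats as constants: incident photons per unit volume `i0`, beam area
#' `area` and the solid angle `theta` subtended at the detector.
#'
#' @param r sphere radius, cm (> 0).
#' @param i0 incident photons per unit volume, arbitrary units (> 0).
#' @param area beam area, cm^2 (> 0).
#' @param theta solid angle, steradians, in (0, 4*pi].
#' @return An object of class `scatter_geometry`.
#' @export
scatter_geometry <- function(r, i0 = 1, area = 1, theta = 1) {
  if (!is.numeric(r) || r <= 0) stop("'r' must be positive (cm)")
  if (area <= 0) stop("'area' must be positive (cm^2)")
  if (theta <= 0 || theta > 4 * pi) stop("'theta' must lie in (0, 4*pi]")
  if (i0 <= 0) stop("'i0' must be positive")
  structure(list(r = r, i0 = i0, area = area, theta = theta),
            class = "scatter_geometry")
}

#' Differential scatter intensity at radius r
#'
#' Photons scattered from a shell at radius `r` of a homogeneous sphere
#' contribute
#' \deqn{dI_s(r) = \frac{I}{A}\,\exp(-\mu r)\,\rho_e\,\theta}
#' per unit radius, with beam intensity `I`, beam area `A` and solid
#' angle `theta` held constant. Integrating over `r` in \[0, R\] gives
#' `(I/A) * theta * rho_e * (1 - exp(-mu R)) / mu` (and `... * R` in the
#' `mu -> 0` limit); see [scatter_intensity_integral()].
#'
#' @param geom a [scatter_geometry()].
#' @param mu linear attenuation coefficient, cm^-1 (>= 0).
#' @param rho_e relative electron density (>= 0).
#' @param r evaluation radius (or radii), cm (> 0).
#' @return dI_s per unit radius at each `r`.
#' @export
scatter_intensity_differential <- function(geom, mu, rho_e, r) {
  stopifnot(inherits(geom, "scatter_geometry"))
  if (!is.numeric(r) || any(r <= 0)) stop("'r' must be positive (cm)")
  if (mu < 0 || rho_e < 0) stop("'mu' and 'rho_e' must be non-negative")
  (geom$i0 / geom$area) * exp(-mu * r) * rho_e * geom$theta
}

#' Closed-form integral of the differential scatter model
#'
#' Definite integral of [scatter_intensity_differential()] over
#' `r` in \[0, R\].
#'
#' @inheritParams scatter_intensity_differential
#' @param R upper integration radius, cm (> 0).
#' @return Total scatter intensity over the sphere, arbitrary units.
#' @export
scatter_intensity_integral <- function(geom, mu, rho_e, R) {
  stopifnot(inherits(geom, "scatter_geometry"))
  if (!is.numeric(R) || R <= 0) stop("'R' must be positive (cm)")
  if (mu < 0 || rho_e < 0) stop("'mu' and 'rho_e' must be non-negative")
  depth <- if (mu == 0) R else (1 - exp(-mu * R)) / mu
  (geom$i0 / geom$area) * geom$theta * rho_e * depth
}
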