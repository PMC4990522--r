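#' Describe a circular forearm-phantom cross-section
#'
#' The phantom emulates a European Forearm Phantom (QRM-EFP) style test
#' object: a resin water-equivalent body, one cortical ring of
#' high-mineral bone-equivalent material, and a centred trabecular insert
#' inside the ring. The cross-section is circular; one insert is
#' simulated per stack.
#'
#' @param outer_radius outer radius of the cortical ring, mm.
#' @param cortical_wall_thickness cortical wall thickness, mm; the QRM-EFP
#'   sections are 1.2 and 2.5 mm.
#' @param cortical_material a [material_spec()]; default 800 mg HA cm^-3.
#' @param trabecular_material a [material_spec()] for the insert.
#' @param body_material a [material_spec()]; default water-equivalent.
#' @param body_radius radius of the water-equivalent body, mm.
#' @param center insert centre offset from the grid centre, mm (x, y).
#' @param contour_hu periosteal contouring threshold the phantom must be
#'   compatible with (cortical HU above it, body and insert below), HU.
#' @return An object of class `phantom_spec`.
#' @seealso [default_qrm_efp()] for the standard configuration.
#' @export
phantom_spec <- function(outer_radius = 10,
                         cortical_wall_thickness = 1.2,
                         cortical_material = material_spec("cortical", 800),
                         trabecular_material = material_spec("trabecular", 50),
                         body_material = material_spec("water", 0),
                         body_radius = 20,
                         center = c(0, 0),
                         contour_hu = 900) {
  stopifnot(inherits(cortical_material, "material_spec"),
            inherits(trabecular_material, "material_spec"),
            inherits(body_material, "material_spec"))
  if (!is.numeric(outer_radius) || outer_radius <= 0)
    stop("'outer_radius' must be positive (mm)")
  if (!is.numeric(cortical_wall_thickness) ||
      cortical_wall_thickness <= 0 || cortical_wall_thickness >= outer_radius)
    stop("'cortical_wall_thickness' must lie in (0, outer_radius)")
  if (body_radius <= outer_radius)
    stop("'body_radius' must exceed 'outer_radius'")
  if (length(center) != 2L || !is.numeric(center))
    stop("'center' must be numeric length 2 (mm)")
  if (cortical_material$hu <= contour_hu)
    stop(sprintf("cortical material (%g HU) must exceed the contour threshold (%g HU)",
                 cortical_material$hu, contour_hu))
  if (trabecular_material$hu >= contour_hu || body_material$hu >= contour_hu)
    stop("body and trabecular materials must stay below the contour threshold")
  structure(
    list(outer_radius = outer_radius,
         cortical_wall_thickness = cortical_wall_thickness,
         cortical_material = cortical_material,
         trabecular_material = trabecular_material,
         body_material = body_material,
         body_radius = body_radius,
         center = as.numeric(center),
         contour_hu = contour_hu),
    class = "phantom_spec")
}

#' Standard QRM-EFP-like phantom
#'
#' Convenience constructor for the default forearm phantom: water body,
#' 800 mg HA cm^-3 cortical ring of 1.2 mm (2.5 mm selectable) wall, and
#' a trabecular insert at the requested hydroxyapatite density. The
#' QRM-EFP insert densities are 200, 100 and 50 mg HA cm^-3 plus water.
#'
#' @param trabecular_rho_ha insert density, mg HA cm^-3, in \[0, 800\].
#' @param wall cortical wall thickness, mm (1.2 or 2.5 in the physical
#'   phantom; any value in (0, outer_radius) is accepted).
#' @param trabecular_rho_e optional explicit relative electron density for
#'   the insert, overriding the default density model.
#' @param ... further arguments passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @examples
#' default_qrm_efp(50)          # low-density trabecular insert
#' default_qrm_efp(0)           # water-equivalent insert
#' @export
default_qrm_efp <- function(trabecular_rho_ha, wall = 1.2,
                            trabecular_rho_e = NULL, ...) {
  if (!is.numeric(trabecular_rho_ha) || length(trabecular_rho_ha) != 1L ||
      !is.finite(trabecular_rho_ha) ||
      trabecular_rho_ha < 0 || trabecular_rho_ha > 800)
    stop("'trabecular_rho_ha' must lie in [0, 800] mg HA cm^-3")
  phantom_spec(
    cortical_wall_thickness = wall,
    trabecular_material = material_spec("trabecular", trabecular_rho_ha,
                                        rho_e = trabecular_rho_e),
    ...)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    paste0("<phantom_spec> ring r = %g mm, wall %g mm (%s), insert %s",
           " (rho_e %g), body r = %g mm\n"),
    x$outer_radius, x$cortical_wall_thickness, x$cortical_material$name,
    x$trabecular_material$name, x$trabecular_material$rho_e, x$body_radius))
  invisible(x)
}

#' Acquisition parameters for a simulated CBCT scan
#'
#' Tube settings are carried as metadata (the simulator is monochromatic
#' at one effective energy); the geometric fields control rendering, and
#' `s_per_electron` is the average scatter intensity per electron in the
#' scatter model.
#'
#' @param kvp tube voltage, kVp (metadata).
#' @param ma tube current, mA (metadata).
#' @param exposure_ms exposure time, ms (metadata).
#' @param energy effective photon energy, keV; materials carry mu at this
#'   energy as a scalar.
#' @param matrix_size pixels per image side (>= 16).
#' @param pixel_spacing in-plane pixel size, mm.
#' @param slice_thickness slice thickness, mm.
#' @param s_per_electron average scatter intensity per electron, arbitrary
#'   units (> 0).
#' @return An object of class `scan_params`.
#' @export
scan_params <- function(kvp = 130, ma = 10, exposure_ms = 20, energy = 65,
                        matrix_size = 1024, pixel_spacing = 0.1,
                        slice_thickness = 0.2162, s_per_electron = 1) {
  if (!is.numeric(matrix_size) || matrix_size < 16)
    stop("'matrix_size' must be >= 16")
  if (pixel_spacing <= 0) stop("'pixel_spacing' must be positive (mm)")
  if (slice_thickness <= 0) stop("'slice_thickness' must be positive (mm)")
  if (s_per_electron <= 0) stop("'s_per_electron' must be positive")
  structure(
    list(kvp = kvp, ma = ma, exposure_ms = exposure_ms, energy = energy,
         matrix_size = as.integer(matrix_size),
         pixel_spacing = pixel_spacing,
         slice_thickness = slice_thickness,
         s_per_electron = s_per_electron),
    class = "scan_params")
}
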