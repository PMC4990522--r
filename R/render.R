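#' Streak-artifact generator parameters
#'
#' The simulator carries the density signal in the *number* of streaks: a
#' slice receives `round(gain * I_s)` radial streaks, where `I_s` is the
#' scatter intensity of the trabecular insert ([scatter_intensity()]).
#' Each streak runs outward from the cortical ring at a random angle; its
#' pixels take a bright HU drawn uniformly from `bright_hu_range`,
#' decaying with distance over `decay_length_mm`, flanked by dark bands
#' offset by `dark_hu_offset`. Rays are truncated once the bright value
#' falls below 300 HU (below the 500-900 HU counting range). Dark bands
#' do not stack across streaks (a pixel takes its single strongest band)
#' and never erase bright streak pixels, matching the appearance of
#' bright streaks with dark streaks running between them.
#'
#' @param gain streaks per unit scatter intensity (> 0).
#' @param bright_hu_range HU interval bright-streak peak values are drawn
#'   from; must overlap the 500-900 HU sweep interval so that pixel
#'   counting is sensitive to the streaks.
#' @param dark_hu_offset negative HU delta applied to the flanking dark
#'   bands.
#' @param streak_width_px width of the bright ray, pixels; dark bands sit
#'   immediately outside it.
#' @param decay_length_mm exponential decay length of streak amplitude, mm.
#' @param seed RNG seed for streak angles and peak values.
#' @return An object of class `streak_params`.
#' @export
streak_params <- function(gain = 10, bright_hu_range = c(500, 1100),
                          dark_hu_offset = -600, streak_width_px = 1,
                          decay_length_mm = 6, seed = 1L) {
  if (!is.numeric(gain) || gain <= 0) stop("'gain' must be positive")
  if (length(bright_hu_range) != 2L || diff(bright_hu_range) <= 0)
    stop("'bright_hu_range' must be an increasing HU interval")
  if (bright_hu_range[2] < 500 || bright_hu_range[1] > 900)
    stop("'bright_hu_range' must overlap the sweep interval [500, 900] HU")
  if (bright_hu_range[2] > 3071) stop("'bright_hu_range' exceeds the HU range")
  if (dark_hu_offset >= 0) stop("'dark_hu_offset' must be negative")
  if (streak_width_px < 1) stop("'streak_width_px' must be >= 1")
  if (decay_length_mm <= 0) stop("'decay_length_mm' must be positive (mm)")
  structure(
    list(gain = gain, bright_hu_range = as.numeric(bright_hu_range),
         dark_hu_offset = dark_hu_offset,
         streak_width_px = as.integer(streak_width_px),
         decay_length_mm = decay_length_mm, seed = as.integer(seed)),
    class = "streak_params")
}

## squared-distance grid (mm) from the phantom centre, rows = y, cols = x
radius_grid <- function(n, pixel_spacing, center) {
  cc <- (n + 1) / 2
  xs <- ((seq_len(n)) - cc) * pixel_spacing - center[1]
  ys <- ((seq_len(n)) - cc) * pixel_spacing - center[2]
  sqrt(outer(ys^2, xs^2, `+`))
}

#' Render the noise-free phantom slice
#'
#' Deterministic base image: air background at -1000 HU, the
#' water-equivalent body, the cortical ring annulus and the trabecular
#' insert each filled with the HU value of their material
#' ([hu_from_density()]).
#'
#' @param phantom a [phantom_spec()].
#' @param scan a [scan_params()].
#' @return A [slice_image()].
#' @export
render_base_image <- function(phantom, scan) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(scan, "scan_params"))
  fov_half <- scan$matrix_size * scan$pixel_spacing / 2
  if (phantom$body_radius + sqrt(sum(phantom$center^2)) > fov_half)
    stop("phantom does not fit in the field of view")
  n <- scan$matrix_size
  r <- radius_grid(n, scan$pixel_spacing, phantom$center)
  px <- matrix(-1000, n, n)
  px[r <= phantom$body_radius] <- phantom$body_material$hu
  px[r <= phantom$outer_radius] <- phantom$cortical_material$hu
  px[r <= phantom$outer_radius - phantom$cortical_wall_thickness] <-
    phantom$trabecular_material$hu
  slice_image(round(px), scan$pixel_spacing, scan$slice_thickness)
}

## scatter intensity of the trabecular insert as seen by the streak model
insert_scatter_intensity <- function(phantom, scan) {
  r_cm <- (phantom$outer_radius - phantom$cortical_wall_thickness) / 10
  rho_e <- phantom$trabecular_material$rho_e
  if (rho_e == 0) return(0)
  scatter_intensity(phantom$trabecular_material$mu, r_cm, rho_e,
                    scan$s_per_electron)
}

#' Overlay scattered streak artifacts on a base slice
#'
#' Draws `round(gain * I_s)` bright radial streaks from the cortical ring
#' outward, where `I_s` is the insert's scatter intensity — so streak
#' abundance is (up to rounding) linear in the insert's electron density.
#' Streaks only touch pixels exterior to the ring; the insert interior is
#' never modified. Bright pixels take the maximum of their current value
#' and the decayed streak value; dark bands are additive and clamped at
#' -1024 HU. Fully reproducible for a fixed `params$seed`.
#'
#' The streak angles and peak HU values drawn are attached to the result
#' as `attr(, "streaks")` (a data frame) for inspection.
#'
#' @param base a [slice_image()] from [render_base_image()].
#' @param phantom the [phantom_spec()] the base was rendered from.
#' @param scan the [scan_params()] used.
#' @param params a [streak_params()].
#' @return A [slice_image()] with artifacts; `round(gain * I_s)` may be
#'   zero, in which case the base is returned unchanged.
#' @export
render_streak_artifacts <- function(base, phantom, scan, params) {
  stopifnot(inherits(base, "slice_image"), inherits(phantom, "phantom_spec"),
            inherits(scan, "scan_params"), inherits(params, "streak_params"))
  i_s <- insert_scatter_intensity(phantom, scan)
  n_streaks <- round(params$gain * i_s)
  out <- base
  if (n_streaks < 1) {
    attr(out, "streaks") <- data.frame(angle = numeric(0),
                                       peak_hu = numeric(0))
    return(out)
  }
  draws <- with_seed(params$seed, {
    data.frame(angle = stats::runif(n_streaks, 0, 2 * pi),
               peak_hu = stats::runif(n_streaks,
                                      params$bright_hu_range[1],
                                      params$bright_hu_range[2]))
  })

  px <- base$pixels
  n <- nrow(px)
  sp <- base$pixel_spacing
  cc <- (n + 1) / 2
  rmat <- radius_grid(n, sp, phantom$center)
  exterior <- rmat > phantom$outer_radius
  amp_floor <- 300
  r0 <- phantom$outer_radius + 0.5 * sp
  step <- sp / 2
  d_max <- params$decay_length_mm *
    log(params$bright_hu_range[2] / amp_floor)
  d_seq <- seq(0, max(d_max, step), by = step)
  decay <- exp(-d_seq / params$decay_length_mm)
  w_mm <- params$streak_width_px * sp

  ray_idx <- function(angle, lateral) {
    ux <- cos(angle); uy <- sin(angle)
    x <- phantom$center[1] + (r0 + d_seq) * ux - lateral * uy
    y <- phantom$center[2] + (r0 + d_seq) * uy + lateral * ux
    col <- round(cc + x / sp)
    row <- round(cc + y / sp)
    ok <- row >= 1 & row <= n & col >= 1 & col <= n
    idx <- (col[ok] - 1L) * n + row[ok]
    ok2 <- exterior[idx]
    list(idx = idx[ok2], k = which(ok)[ok2])
  }

  ## pass 1 - dark bands: each pixel takes the single strongest band
  ## (no stacking across streaks), added to the base
  dark_delta <- matrix(0, n, n)
  for (i in seq_len(n_streaks)) {
    live <- draws$peak_hu[i] * decay >= amp_floor
    for (side in c(-1, 1)) {
      ray <- ray_idx(draws$angle[i], side * w_mm)
      keep <- live[ray$k] & !duplicated(ray$idx)
      idx <- ray$idx[keep]
      dark <- round(params$dark_hu_offset * decay[ray$k][keep])
      dark_delta[idx] <- pmin(dark_delta[idx], dark)
    }
  }
  px <- px + dark_delta
  px[px < -1024] <- -1024
  ## pass 2 - bright rays on top: bright streaks are never erased by a
  ## neighbouring streak's dark band
  for (i in seq_len(n_streaks)) {
    amp <- draws$peak_hu[i] * decay
    live <- amp >= amp_floor
    ray <- ray_idx(draws$angle[i], 0)
    keep <- live[ray$k] & !duplicated(ray$idx)
    idx <- ray$idx[keep]
    px[idx] <- pmin(3071, pmax(px[idx], round(amp[ray$k][keep])))
  }

  out$pixels <- px
  attr(out, "streaks") <- draws
  out
}

#' Simulate a stack of artifact-bearing phantom slices
#'
#' Renders the deterministic base image once and overlays an independent
#' streak realization per slice. Per-slice RNG seeds are derived as
#' `seed + slice_index`, so slices are independent yet the whole stack is
#' exactly reproducible from the master seed.
#'
#' @param phantom a [phantom_spec()].
#' @param scan a [scan_params()].
#' @param params a [streak_params()]; its `seed` field is ignored in
#'   favour of `seed`.
#' @param n_slices number of slices (>= 1).
#' @param seed master seed.
#' @return A `slice_stack`: a list of [slice_image()] with `slice_index`
#'   0 to `n_slices - 1`.
#' @examples
#' ph <- default_qrm_efp(50)
#' sc <- scan_params(matrix_size = 64, pixel_spacing = 0.8)
#' st <- simulate_stack(ph, sc, streak_params(), n_slices = 3, seed = 42)
#' @export
simulate_stack <- function(phantom, scan, params, n_slices, seed) {
  stopifnot(inherits(params, "streak_params"))
  if (!is.numeric(n_slices) || n_slices < 1)
    stop("'n_slices' must be >= 1")
  n_slices <- as.integer(n_slices)
  base <- render_base_image(phantom, scan)
  slices <- vector("list", n_slices)
  for (k in seq_len(n_slices)) {
    p <- params
    p$seed <- as.integer(seed) + (k - 1L)
    sl <- render_streak_artifacts(base, phantom, scan, p)
    sl$slice_index <- k - 1L
    slices[[k]] <- sl
  }
  new_slice_stack(slices, seed = as.integer(seed))
}
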