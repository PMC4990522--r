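#' A single CT slice in Hounsfield units
#'
#' @param pixels square numeric matrix of HU values; air is -1000. Values
#'   must lie in the representable int16 CT range \[-1024, 3071\].
#' @param pixel_spacing in-plane pixel size, mm.
#' @param slice_thickness slice thickness, mm.
#' @param slice_index ordinal position of the slice in its stack (0-based).
#' @return An object of class `slice_image`.
#' @export
slice_image <- function(pixels, pixel_spacing = 1, slice_thickness = 1,
                        slice_index = 0L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stop("'pixels' must be finite")
  if (min(pixels) < -1024 || max(pixels) > 3071)
    stop("HU values must lie in [-1024, 3071]")
  if (pixel_spacing <= 0 || slice_thickness <= 0)
    stop("'pixel_spacing' and 'slice_thickness' must be positive (mm)")
  structure(
    list(pixels = pixels, pixel_spacing = pixel_spacing,
         slice_thickness = slice_thickness,
         slice_index = as.integer(slice_index)),
    class = "slice_image")
}

#' @export
print.slice_image <- function(x, ...) {
  cat(sprintf("<slice_image> %d x %d px, %g mm/px, %g mm thick, index %d, HU [%d, %d]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_spacing,
              x$slice_thickness, x$slice_index,
              as.integer(min(x$pixels)), as.integer(max(x$pixels))))
  invisible(x)
}

#' @export
plot.slice_image <- function(x, main = NULL, ...) {
  n <- nrow(x$pixels)
  graphics::image(seq_len(n) * x$pixel_spacing,
                  seq_len(ncol(x$pixels)) * x$pixel_spacing,
                  t(x$pixels[n:1, , drop = FALSE]),
                  col = grDevices::gray.colors(256, start = 0, end = 1),
                  asp = 1, xlab = "mm", ylab = "mm",
                  main = main %||% sprintf("slice %d", x$slice_index), ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_slice_stack <- function(slices, seed = NULL) {
  structure(slices, class = "slice_stack", seed = seed)
}

#' @export
print.slice_stack <- function(x, ...) {
  s1 <- x[[1L]]
  cat(sprintf("<slice_stack> %d slices, %d x %d px, %g mm/px, %g mm thick\n",
              length(x), nrow(s1$pixels), ncol(s1$pixels),
              s1$pixel_spacing, s1$slice_thickness))
  invisible(x)
}

## run code under a fixed RNG state without touching the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
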