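#' Hand-checkable toy slices for the measurement chain
#'
#' Deterministic tiny images whose expected segmentation masks and
#' artifact counts were worked out by hand; they exercise the pipeline's
#' contracts without any simulation. Each fixture carries its expected
#' values in `attr(, "expected")`.
#'
#' Registry:
#' \describe{
#'   \item{`ring_8x8`}{8x8, a 5x5 square ring of 1200 HU on 0 HU.
#'     Expected: periosteal 25 px (filled square), wall 16 px,
#'     endosteal 9 px.}
#'   \item{`two_components`}{16x16 with a 5x5 ring (16 px wall) and a
#'     separate 3x3 ring (8 px); only the larger is the periosteal
#'     component. Expected periosteal 25 px.}
#'   \item{`exterior_7px`}{12x12, a 5x5 ring of 1200 HU plus exactly 7
#'     exterior pixels at 600 HU. Expected artifact count 7 at a 500 HU
#'     threshold and 0 at 700 HU.}
#'   \item{`constant_zero`}{8x8 of 0 HU; every mask downstream is empty.}
#' }
#'
#' @param name fixture name from the registry above.
#' @return A [slice_image()] (pixel spacing and thickness 1 mm) with an
#'   `expected` attribute.
#' @examples
#' fx <- make_fixture("ring_8x8")
#' attr(fx, "expected")
#' @export
make_fixture <- function(name) {
  px <- switch(
    name,
    ring_8x8 = {
      m <- matrix(0, 8, 8)
      m[2:6, 2:6] <- 1200
      m[3:5, 3:5] <- 0
      m
    },
    two_components = {
      m <- matrix(0, 16, 16)
      m[2:6, 2:6] <- 1200
      m[3:5, 3:5] <- 0
      m[10:12, 10:12] <- 1200
      m[11, 11] <- 0
      m
    },
    exterior_7px = {
      m <- matrix(0, 12, 12)
      m[4:8, 4:8] <- 1200
      m[5:7, 5:7] <- 0
      for (rc in list(c(1, 1), c(1, 12), c(2, 10), c(10, 2),
                      c(12, 12), c(11, 1), c(6, 11)))
        m[rc[1], rc[2]] <- 600
      m
    },
    constant_zero = matrix(0, 8, 8),
    stop(sprintf("unknown fixture '%s'; see ?make_fixture for the registry",
                 name))
  )
  expected <- switch(
    name,
    ring_8x8 = list(periosteal = 25L, wall = 16L, endosteal = 9L),
    two_components = list(periosteal = 25L, wall = 16L, endosteal = 9L),
    exterior_7px = list(periosteal = 25L, wall = 16L, endosteal = 9L,
                        artifacts_at_500 = 7L, artifacts_at_700 = 0L),
    constant_zero = list(periosteal = 0L)
  )
  out <- slice_image(px, pixel_spacing = 1, slice_thickness = 1)
  attr(out, "expected") <- expected
  out
}
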