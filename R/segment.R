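## ---- binary-mask primitives -------------------------------------------
## Connectivity conventions are fixed package-wide: foreground components
## are 8-connected, hole filling floods the background 4-connected from
## the image border. Both are breadth-first searches with vectorized
## frontiers; matrices are column-major, idx = (col-1)*nrow + row.

neighbour_idx <- function(idx, nr, nc, offsets) {
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  out <- integer(0)
  for (k in seq_len(nrow(offsets))) {
    r2 <- row + offsets[k, 1L]
    c2 <- col + offsets[k, 2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    out <- c(out, (c2[ok] - 1L) * nr + r2[ok])
  }
  unique(out)
}

OFFS8 <- cbind(rep(-1:1, times = 3), rep(-1:1, each = 3))[-5, , drop = FALSE]
OFFS4 <- cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))

#' Label 8-connected components of a binary mask
#'
#' @param mask logical matrix.
#' @return Integer matrix of the same shape; 0 is background, components
#'   are numbered from 1 in column-major discovery order.
#' @keywords internal
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  todo <- mask
  cur <- 0L
  repeat {
    seed <- which(todo)
    if (length(seed) == 0L) break
    cur <- cur + 1L
    frontier <- seed[1L]
    while (length(frontier) > 0L) {
      lab[frontier] <- cur
      todo[frontier] <- FALSE
      nb <- neighbour_idx(frontier, nr, nc, OFFS8)
      frontier <- nb[todo[nb]]
    }
  }
  lab
}

#' Fill interior holes of a binary mask
#'
#' A hole is any background region not 4-connected to the image border.
#'
#' @param mask logical matrix.
#' @return Logical matrix with holes filled.
#' @keywords internal
#' @export
fill_holes <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- !mask
  border <- unique(c(which(bg[1L, ]) * nr - nr + 1L,
                     which(bg[nr, ]) * nr,
                     which(bg[, 1L]),
                     (nc - 1L) * nr + which(bg[, nc])))
  reached <- matrix(FALSE, nr, nc)
  frontier <- border
  while (length(frontier) > 0L) {
    reached[frontier] <- TRUE
    nb <- neighbour_idx(frontier, nr, nc, OFFS4)
    frontier <- nb[bg[nb] & !reached[nb]]
  }
  mask | (bg & !reached)
}

## ---- contour extraction ------------------------------------------------

new_contour_set <- function(periosteal, endosteal = NULL, wall = NULL,
                            contour_hu = NA_real_) {
  structure(list(periosteal_mask = periosteal, endosteal_mask = endosteal,
                 wall_mask = wall, contour_hu = contour_hu),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set> periosteal %d px", sum(x$periosteal_mask)))
  if (!is.null(x$wall_mask))
    cat(sprintf(", wall %d px, endosteal %d px",
                sum(x$wall_mask), sum(x$endosteal_mask)))
  cat(sprintf(" (contour threshold %g HU)\n", x$contour_hu))
  invisible(x)
}

#' Extract the periosteal region by HU thresholding
#'
#' Binarizes the slice at `hu_threshold` (900 HU by default, the value
#' used to delineate mineralized cortical bone from extra-osseal soft
#' tissue), keeps the largest 8-connected component and fills its interior
#' holes. The filled region — cortical wall plus everything it encloses —
#' is the periosteal mask. If no pixel clears the threshold an empty mask
#' is returned (not an error).
#'
#' @param image a [slice_image()].
#' @param hu_threshold periosteal contouring threshold, HU.
#' @return A `contour_set` with `periosteal_mask` set; pass it to
#'   [extract_endosteal()] to split wall from marrow.
#' @export
extract_periosteal <- function(image, hu_threshold = 900) {
  stopifnot(inherits(image, "slice_image"))
  bw <- image$pixels >= hu_threshold
  if (!any(bw))
    return(new_contour_set(bw, contour_hu = hu_threshold))
  lab <- label_components(bw)
  sizes <- tabulate(lab[lab > 0L])
  largest <- lab == which.max(sizes)  # ties: lowest label, discovery order
  new_contour_set(fill_holes(largest), contour_hu = hu_threshold)
}

#' Extract the endosteal region inside a periosteal contour
#'
#' Splits the periosteal region into the mineralized cortical wall (the
#' thresholded pixels) and the endosteal/marrow compartment (everything
#' the wall encloses that falls below the contour threshold). By
#' construction `wall` and `endosteal` partition the periosteal mask.
#'
#' @param image the [slice_image()] the contours were computed from.
#' @param contours a `contour_set` from [extract_periosteal()].
#' @return The `contour_set` with `endosteal_mask` and `wall_mask` filled
#'   in.
#' @export
extract_endosteal <- function(image, contours) {
  stopifnot(inherits(image, "slice_image"), inherits(contours, "contour_set"))
  check_mask_shape(image, contours$periosteal_mask)
  if (!any(contours$periosteal_mask))
    stop("periosteal mask is empty; nothing to split")
  wall <- contours$periosteal_mask & (image$pixels >= contours$contour_hu)
  contours$wall_mask <- wall
  contours$endosteal_mask <- contours$periosteal_mask & !wall
  contours
}

#' Isolate scattered-artifact pixels outside the periosteal surface
#'
#' Subtracts the whole area inside the periosteal surface so that only
#' scattered image artifacts remain, then keeps exterior pixels at or
#' above `hu_min`. The result is disjoint from the periosteal mask by
#' construction.
#'
#' @param image a [slice_image()].
#' @param contours a `contour_set` computed from the same image.
#' @param hu_min counting threshold, HU.
#' @return An object of class `artifact_map` with fields `mask` (logical
#'   matrix) and `source_slice`.
#' @export
isolate_artifacts <- function(image, contours, hu_min) {
  stopifnot(inherits(image, "slice_image"), inherits(contours, "contour_set"))
  check_mask_shape(image, contours$periosteal_mask)
  mask <- (image$pixels >= hu_min) & !contours$periosteal_mask
  structure(list(mask = mask, source_slice = image$slice_index,
                 hu_min = hu_min),
            class = "artifact_map")
}

#' @export
print.artifact_map <- function(x, ...) {
  cat(sprintf("<artifact_map> %d artifact px (>= %g HU) in slice %d\n",
              sum(x$mask), x$hu_min, x$source_slice))
  invisible(x)
}

check_mask_shape <- function(image, mask) {
  if (!identical(dim(image$pixels), dim(mask)))
    stop("mask shape does not match the image")
  invisible(TRUE)
}
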