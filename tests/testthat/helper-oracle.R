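# Brute-force per-pixel reimplementation of the measurement chain,
# deliberately naive (fixed-point label propagation), used as an
# independent oracle on small images.

brute_label8 <- function(bw) {
  nr <- nrow(bw); nc <- ncol(bw)
  lab <- matrix(0L, nr, nc)
  lab[bw] <- which(bw)  # provisional: own linear index
  repeat {
    changed <- FALSE
    for (j in seq_len(nc)) for (i in seq_len(nr)) {
      if (!bw[i, j]) next
      best <- lab[i, j]
      for (dj in -1:1) for (di in -1:1) {
        i2 <- i + di; j2 <- j + dj
        if (i2 >= 1 && i2 <= nr && j2 >= 1 && j2 <= nc && bw[i2, j2])
          best <- min(best, lab[i2, j2])
      }
      if (best < lab[i, j]) { lab[i, j] <- best; changed <- TRUE }
    }
    if (!changed) break
  }
  lab
}

brute_fill4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  outside <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    if ((i == 1 || i == nr || j == 1 || j == nc) && !mask[i, j])
      outside[i, j] <- TRUE
  repeat {
    changed <- FALSE
    for (j in seq_len(nc)) for (i in seq_len(nr)) {
      if (mask[i, j] || outside[i, j]) next
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        i2 <- i + d[1]; j2 <- j + d[2]
        if (i2 >= 1 && i2 <= nr && j2 >= 1 && j2 <= nc && outside[i2, j2]) {
          outside[i, j] <- TRUE; changed <- TRUE; break
        }
      }
    }
    if (!changed) break
  }
  mask | (!mask & !outside)
}

# periosteal mask by the documented rule: threshold, largest 8-connected
# component (ties to the component holding the smallest linear index),
# fill 4-connected holes
brute_periosteal <- function(pixels, contour_hu = 900) {
  bw <- pixels >= contour_hu
  if (!any(bw)) return(bw)
  lab <- brute_label8(bw)
  ids <- sort(unique(lab[lab > 0L]))  # ascending = discovery order
  sizes <- vapply(ids, function(id) sum(lab == id), integer(1))
  brute_fill4(lab == ids[which.max(sizes)])
}

brute_count <- function(pixels, hu_min, contour_hu = 900) {
  peri <- brute_periosteal(pixels, contour_hu)
  sum(pixels >= hu_min & !peri)
}

# small simulated slice used by several property tests
tiny_scan <- function(matrix_size = 128, pixel_spacing = 0.4)
  scan_params(matrix_size = matrix_size, pixel_spacing = pixel_spacing)
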