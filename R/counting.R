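#' Count artifact pixels per slice
#'
#' For each slice: extract the periosteal region at `contour_hu`
#' ([extract_periosteal()]), subtract it, and count exterior pixels at or
#' above `hu_threshold` ([isolate_artifacts()]).
#'
#' @param stack a `slice_stack` or list of [slice_image()].
#' @param hu_threshold counting threshold, HU.
#' @param contour_hu periosteal contouring threshold, HU.
#' @return Integer vector of per-slice artifact-pixel counts, in slice
#'   order.
#' @export
count_artifact_pixels <- function(stack, hu_threshold, contour_hu = 900) {
  stack <- as_slice_list(stack)
  vapply(stack, function(sl) {
    contours <- extract_periosteal(sl, contour_hu)
    sum(isolate_artifacts(sl, contours, hu_threshold)$mask)
  }, integer(1))
}

as_slice_list <- function(stack) {
  if (inherits(stack, "slice_image")) stack <- list(stack)
  if (!is.list(stack) || length(stack) == 0L ||
      !all(vapply(stack, inherits, logical(1), "slice_image")))
    stop("'stack' must be a non-empty list of slice_image objects")
  stack
}

## per-slice counts for many thresholds at once: the periosteal contour
## depends only on contour_hu, so it is computed once per slice
counts_by_threshold <- function(stack, thresholds, contour_hu) {
  stack <- as_slice_list(stack)
  out <- matrix(0L, nrow = length(stack), ncol = length(thresholds))
  for (i in seq_along(stack)) {
    sl <- stack[[i]]
    peri <- extract_periosteal(sl, contour_hu)$periosteal_mask
    ext <- sl$pixels[!peri]
    out[i, ] <- vapply(thresholds, function(t) sum(ext >= t), integer(1))
  }
  out
}

#' Sweep the counting threshold over two stacks and difference the counts
#'
#' The measurement at the heart of the method: artifact pixels in a
#' low-density and a high-density stack are enumerated at each threshold
#' (500-900 HU in steps of 20 by default), summed over slices, and the
#' per-threshold difference taken. The threshold maximizing the
#' difference is reported as `optimal_threshold` (ties resolve to the
#' lowest HU, which retains the most signal).
#'
#' The difference is `high - low` by default; the `sign` flag flips it.
#'
#' @param stack_low,stack_high `slice_stack`s (or lists of
#'   [slice_image()]) for the low- and high-density material.
#' @param thresholds ascending HU thresholds to sweep.
#' @param contour_hu periosteal contouring threshold, HU.
#' @param sign `"high_minus_low"` (default) or `"low_minus_high"`.
#' @return An object of class `sweep_result`: a list with `table` (data
#'   frame with columns `threshold`, `count_low`, `count_high`, `diff`),
#'   `optimal_threshold`, `sign`, and per-slice count matrices
#'   `per_slice_low` / `per_slice_high` (slices x thresholds).
#' @export
threshold_sweep <- function(stack_low, stack_high,
                            thresholds = seq(500, 900, by = 20),
                            contour_hu = 900,
                            sign = c("high_minus_low", "low_minus_high")) {
  sign <- match.arg(sign)
  if (length(thresholds) == 0L)
    stop("'thresholds' must be non-empty")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("'thresholds' must be strictly ascending")
  low <- counts_by_threshold(stack_low, thresholds, contour_hu)
  high <- counts_by_threshold(stack_high, thresholds, contour_hu)
  count_low <- colSums(low)
  count_high <- colSums(high)
  d <- if (sign == "high_minus_low") count_high - count_low else
    count_low - count_high
  tab <- data.frame(threshold = thresholds, count_low = count_low,
                    count_high = count_high, diff = d)
  structure(
    list(table = tab,
         optimal_threshold = thresholds[which.max(d)],
         sign = sign,
         per_slice_low = low, per_slice_high = high),
    class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d thresholds (%g-%g HU), diff = %s\n",
              nrow(x$table), min(x$table$threshold), max(x$table$threshold),
              x$sign))
  cat(sprintf("  optimal threshold %g HU: count_low = %d, count_high = %d, diff = %d\n",
              x$optimal_threshold,
              x$table$count_low[x$table$threshold == x$optimal_threshold],
              x$table$count_high[x$table$threshold == x$optimal_threshold],
              x$table$diff[x$table$threshold == x$optimal_threshold]))
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, ...) {
  plot(x$table$threshold, x$table$diff, type = "b", pch = 16,
       xlab = "threshold (HU)", ylab = sprintf("count diff (%s)", x$sign),
       ...)
  graphics::abline(v = x$optimal_threshold, lty = 2)
  invisible(x)
}

#' Summarize a distribution of per-slice artifact counts
#'
#' Mean, standard deviation and the percentile ladder used to display
#' per-group count distributions (5th/95th, 10th/90th, 25th/75th and the
#' median). The standard deviation uses the population convention
#' (denominator `n`); percentiles use linear interpolation
#' (`stats::quantile` type 7).
#'
#' @param counts numeric vector of per-slice artifact counts (length >= 1).
#' @return An object of class `count_summary`: list with `mean`, `sd`,
#'   `percentiles` (named p5, p10, p25, p50, p75, p90, p95) and `n`.
#' @export
summarize_counts <- function(counts) {
  if (length(counts) == 0L || !is.numeric(counts) || any(!is.finite(counts)))
    stop("'counts' must be a non-empty finite numeric vector")
  p <- stats::quantile(counts, c(.05, .10, .25, .50, .75, .90, .95),
                       names = FALSE, type = 7)
  names(p) <- c("p5", "p10", "p25", "p50", "p75", "p90", "p95")
  structure(
    list(mean = mean(counts),
         sd = sqrt(mean((counts - mean(counts))^2)),
         percentiles = p,
         n = length(counts)),
    class = "count_summary")
}

#' @export
print.count_summary <- function(x, ...) {
  cat(sprintf("<count_summary> n = %d, mean = %.1f, sd = %.1f (population)\n",
              x$n, x$mean, x$sd))
  print(round(x$percentiles, 1))
  invisible(x)
}
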