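#' Fit a linear count-to-density calibration
#'
#' The scatter model is linear in electron density at fixed geometry, so
#' artifact counts against known insert densities are fitted with an
#' ordinary least-squares line `count = slope * density + intercept`
#' (via [stats::lm()]). The residual standard deviation uses the usual
#' `n - 2` denominator; with exactly two calibration points it has no
#' residual degrees of freedom and is reported as `NA`.
#'
#' @param density known densities (mg HA cm^-3, or relative electron
#'   density — any single consistent scale). Alternatively a data frame
#'   with columns `density` and `count` as the only argument.
#' @param count mean artifact counts paired with `density`.
#' @return An object of class `bmd_calibration` with fields `slope`,
#'   `intercept`, `residual_sd`, `n_points` and the underlying `lm` fit.
#'   Supports `print`, `summary`, `coef` and `predict` (density ->
#'   expected count).
#' @examples
#' fit_calibration(c(0, 100), c(10, 20))   # slope 0.1, intercept 10
#' @seealso [estimate_density()] for the inverse prediction.
#' @export
fit_calibration <- function(density, count) {
  if (is.data.frame(density)) {
    if (!all(c("density", "count") %in% names(density)))
      stop("data frame input needs columns 'density' and 'count'")
    count <- density$count
    density <- density$density
  }
  if (length(density) != length(count) || length(density) < 2L)
    stop("need >= 2 (density, count) pairs of equal length")
  if (any(!is.finite(density)) || any(!is.finite(count)))
    stop("calibration pairs must be finite")
  if (length(unique(density)) < 2L)
    stop("degenerate design: all calibration densities are identical")
  fit <- stats::lm(count ~ density,
                   data = data.frame(density = density, count = count))
  sigma <- if (stats::df.residual(fit) > 0)
    sqrt(sum(stats::residuals(fit)^2) / stats::df.residual(fit)) else NA_real_
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         residual_sd = sigma,
         n_points = length(density),
         fit = fit),
    class = "bmd_calibration")
}

#' @export
print.bmd_calibration <- function(x, ...) {
  cat(sprintf("<bmd_calibration> count = %.4g * density + %.4g  (n = %d, residual sd = %.4g)\n",
              x$slope, x$intercept, x$n_points, x$residual_sd))
  invisible(x)
}

#' @export
coef.bmd_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.bmd_calibration <- function(object, ...) summary(object$fit, ...)

#' @export
predict.bmd_calibration <- function(object, density, ...) {
  object$intercept + object$slope * density
}

#' Estimate density from an artifact count (inverse prediction)
#'
#' Inverts the calibration line: `density = (count - intercept) / slope`.
#' The reported uncertainty is the simple inverse-prediction standard
#' deviation `residual_sd / |slope|`. Estimates below zero are physically
#' impossible and are reported as-is but flagged.
#'
#' @param count artifact-pixel count(s).
#' @param model a [fit_calibration()] object with non-zero slope.
#' @return Data frame with columns `count`, `density`, `sd` and
#'   `negative` (logical flag).
#' @export
estimate_density <- function(count, model) {
  stopifnot(inherits(model, "bmd_calibration"))
  if (model$slope == 0)
    stop("calibration slope is zero: density is unidentifiable")
  if (!is.numeric(count) || any(!is.finite(count)))
    stop("'count' must be finite numeric")
  density <- (count - model$intercept) / model$slope
  data.frame(count = count, density = density,
             sd = model$residual_sd / abs(model$slope),
             negative = density < 0)
}

#' Classify a count as low or normal bone mineral density
#'
#' Binary screening rule mirroring the two-cohort comparison between
#' osteoporosis patients and healthy subjects: fewer scattered artifacts
#' indicates lower density. A count strictly below the cutoff is
#' `low_bmd`; a count equal to the cutoff is assigned to `normal`
#' (boundary convention, documented here). When the two cohort means are
#' supplied instead of a cutoff, the cutoff defaults to their midpoint.
#'
#' @param count artifact-pixel count(s).
#' @param cutoff positive decision cutoff in counts, or `NULL` to derive
#'   it from `cohort_means`.
#' @param cohort_means optional numeric length-2: mean counts of the two
#'   calibration cohorts; the cutoff is their midpoint.
#' @return Factor with levels `low_bmd`, `normal`.
#' @examples
#' classify_bmd(c(100, 250), cutoff = 200)
#' @export
classify_bmd <- function(count, cutoff = NULL, cohort_means = NULL) {
  if (is.null(cutoff)) {
    if (is.null(cohort_means) || length(cohort_means) != 2L)
      stop("supply 'cutoff' or two 'cohort_means'")
    cutoff <- mean(cohort_means)
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("'cutoff' must be a single positive count")
  factor(ifelse(count < cutoff, "low_bmd", "normal"),
         levels = c("low_bmd", "normal"))
}
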