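test_that("calibration recovers exact lines", {
  m <- fit_calibration(c(0, 100), c(10, 20))
  expect_equal(m$slope, 0.1)
  expect_equal(m$intercept, 10)
  expect_equal(m$n_points, 2L)
  expect_true(is.na(m$residual_sd))  # no residual degrees of freedom
  # noise-free line: machine-precision recovery, zero residual sd
  d <- c(0, 50, 100, 200)
  m2 <- fit_calibration(d, 2 * d + 5)
  expect_equal(m2$slope, 2, tolerance = 1e-12)
  expect_equal(m2$intercept, 5, tolerance = 1e-12)
  expect_equal(m2$residual_sd, 0, tolerance = 1e-10)
  expect_equal(unname(coef(m2)), c(5, 2), tolerance = 1e-12)
  expect_equal(predict(m2, 75), 155, tolerance = 1e-12)
  expect_error(fit_calibration(c(100, 100, 100), c(1, 2, 3)), "degenerate")
  expect_error(fit_calibration(c(0), c(1)), ">= 2")
})

test_that("inverse prediction inverts the calibration line", {
  m <- fit_calibration(c(0, 100), c(10, 20))
  expect_equal(estimate_density(20, m)$density, 100)
  expect_equal(estimate_density(10, m)$density, 0)  # count = intercept
  # identity on the calibration line for a noisy fit
  set.seed(8)
  d <- c(0, 50, 100, 200)
  m2 <- fit_calibration(d, 3 * d + 40 + rnorm(4, sd = 2))
  expect_equal(estimate_density(predict(m2, 130), m2)$density, 130,
               tolerance = 1e-10)
  # negative estimates are reported but flagged
  est <- estimate_density(5, m)
  expect_true(est$negative)
  expect_lt(est$density, 0)
  zero <- m; zero$slope <- 0
  expect_error(estimate_density(10, zero), "unidentifiable")
})

test_that("simulated calibration has a positive slope", {
  sc <- tiny_scan()
  p <- streak_params(gain = 60)
  counts <- vapply(c(0, 100, 200), function(d) {
    stk <- simulate_stack(default_qrm_efp(d), sc, p, 5, seed = 17)
    mean(count_artifact_pixels(stk, 500))
  }, numeric(1))
  m <- fit_calibration(c(0, 100, 200), counts)
  expect_gt(m$slope, 0)
})

test_that("classification maps counts below the cutoff to low BMD", {
  expect_equal(as.character(classify_bmd(100, cutoff = 200)), "low_bmd")
  expect_equal(as.character(classify_bmd(300, cutoff = 200)), "normal")
  # boundary convention: count equal to the cutoff is normal
  expect_equal(as.character(classify_bmd(200, cutoff = 200)), "normal")
  # midpoint cutoff from two cohort means
  expect_equal(as.character(classify_bmd(c(140, 160),
                                         cohort_means = c(100, 200))),
               c("low_bmd", "normal"))
  expect_error(classify_bmd(100, cutoff = 0), "positive")
  expect_error(classify_bmd(100), "cutoff")
})
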