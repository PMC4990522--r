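test_that("per-slice counting walks the fixture stack", {
  fx <- make_fixture("exterior_7px")
  stack <- list(fx, fx, fx)
  expect_identical(count_artifact_pixels(stack, 500), c(7L, 7L, 7L))
  expect_identical(count_artifact_pixels(stack, 5000), c(0L, 0L, 0L))
  expect_error(count_artifact_pixels(list(), 500), "non-empty")
})

test_that("counts are non-increasing in the threshold, slice by slice", {
  ph <- default_qrm_efp(100)
  sc <- tiny_scan(64, 0.8)
  stk <- simulate_stack(ph, sc, streak_params(gain = 20), 5, seed = 13)
  thresholds <- seq(500, 900, by = 20)
  counts <- vapply(thresholds, function(t) count_artifact_pixels(stk, t),
                   integer(length(stk)))
  for (i in seq_along(stk))
    expect_true(all(diff(counts[i, ]) <= 0))
})

test_that("the default sweep covers 500-900 HU in 21 steps", {
  fx <- make_fixture("exterior_7px")
  sw <- threshold_sweep(list(fx), list(fx))
  expect_equal(sw$table$threshold, seq(500, 900, by = 20))
  expect_equal(nrow(sw$table), 21)
})

test_that("identical stacks difference to zero and ties break low", {
  fx <- make_fixture("exterior_7px")
  sw <- threshold_sweep(list(fx, fx), list(fx, fx))
  expect_true(all(sw$table$diff == 0))
  expect_equal(sw$optimal_threshold, 500)  # all tied: lowest HU wins
  expect_error(threshold_sweep(list(fx), list(fx), thresholds = numeric(0)),
               "non-empty")
})

test_that("the sweep difference follows the density ordering", {
  sc <- tiny_scan()
  p <- streak_params(gain = 10)
  low <- simulate_stack(default_qrm_efp(0), sc, p, 40, seed = 42)
  high <- simulate_stack(default_qrm_efp(0, trabecular_rho_e = 1.2), sc, p,
                         40, seed = 1042)
  sw <- threshold_sweep(low, high)
  # where the denser stack still counts anything, it counts more
  active <- sw$table$count_high > 0
  expect_true(any(active))
  expect_true(all(sw$table$diff[active] > 0))
  # brute-force spot check of the counts feeding the sweep
  i <- which(sw$table$threshold == sw$optimal_threshold)
  expect_equal(sw$table$count_low[i],
               sum(vapply(low, function(sl)
                 brute_count(sl$pixels, sw$optimal_threshold),
                 integer(1))))
  # sign flag flips the subtraction
  sw2 <- threshold_sweep(low, high, sign = "low_minus_high")
  expect_equal(sw2$table$diff, -sw$table$diff)
  # pipeline determinism: same stacks in, same result out
  expect_identical(threshold_sweep(low, high)$table, sw$table)
})

test_that("count summaries report population sd and ordered percentiles", {
  s <- summarize_counts(c(5, 5, 5, 5))
  expect_equal(s$mean, 5)
  expect_equal(s$sd, 0)
  expect_true(all(s$percentiles == 5))
  # linear interpolation on the integer ramp
  expect_equal(summarize_counts(1:100)$percentiles[["p50"]], 50.5)
  # population convention: denominator n
  expect_equal(summarize_counts(c(1, 2, 3, 4))$sd, sqrt(1.25))
  # ordered percentile invariant on random inputs
  set.seed(3)
  for (rep in 1:10) {
    p <- summarize_counts(rpois(25, 40))$percentiles
    expect_true(all(diff(p) >= 0))
  }
  expect_error(summarize_counts(numeric(0)), "non-empty")
})
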