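test_that("periosteal extraction fills the ring fixture", {
  fx <- make_fixture("ring_8x8")
  cs <- extract_periosteal(fx)
  expect_equal(sum(cs$periosteal_mask), 25)   # filled 5x5 square
  expect_true(all(cs$periosteal_mask[2:6, 2:6]))
  cs <- extract_endosteal(fx, cs)
  expect_equal(sum(cs$wall_mask), 16)
  expect_equal(sum(cs$endosteal_mask), 9)
  expect_true(all(cs$endosteal_mask[3:5, 3:5]))
})

test_that("only the largest connected component is retained", {
  fx <- make_fixture("two_components")
  cs <- extract_periosteal(fx)
  expect_equal(sum(cs$periosteal_mask), 25)
  expect_false(any(cs$periosteal_mask[10:12, 10:12]))
})

test_that("images with nothing above threshold give empty masks, not errors", {
  fx <- make_fixture("constant_zero")
  cs <- extract_periosteal(fx)
  expect_equal(sum(cs$periosteal_mask), 0)
  expect_error(extract_endosteal(fx, cs), "empty")
})

test_that("a solid block has no endosteal compartment", {
  m <- matrix(0, 8, 8); m[2:6, 2:6] <- 1200
  img <- slice_image(m)
  cs <- extract_endosteal(img, extract_periosteal(img))
  expect_equal(sum(cs$periosteal_mask), 25)
  expect_equal(sum(cs$endosteal_mask), 0)
  expect_equal(sum(cs$wall_mask), 25)
})

test_that("wall and endosteal masks partition the periosteal mask", {
  for (name in c("ring_8x8", "two_components", "exterior_7px")) {
    fx <- make_fixture(name)
    cs <- extract_endosteal(fx, extract_periosteal(fx))
    expect_identical(cs$wall_mask | cs$endosteal_mask, cs$periosteal_mask)
    expect_false(any(cs$wall_mask & cs$endosteal_mask))
  }
})

test_that("artifact isolation counts exterior pixels only", {
  fx <- make_fixture("exterior_7px")
  cs <- extract_periosteal(fx)
  expect_equal(sum(isolate_artifacts(fx, cs, 500)$mask), 7)
  expect_equal(sum(isolate_artifacts(fx, cs, 700)$mask), 0)
  # artifacts inside the periosteal surface are subtracted
  m <- matrix(0, 8, 8); m[2:6, 2:6] <- 1200; m[4, 4] <- 600
  img <- slice_image(m)
  am <- isolate_artifacts(img, extract_periosteal(img), 500)
  expect_equal(sum(am$mask), 0)
  # shape mismatch is a contract violation
  other <- extract_periosteal(make_fixture("exterior_7px"))
  expect_error(isolate_artifacts(img, other, 500), "shape")
})

test_that("artifact maps are always disjoint from the periosteal mask", {
  ph <- default_qrm_efp(100)
  sc <- tiny_scan(64, 0.8)
  stk <- simulate_stack(ph, sc, streak_params(gain = 20), 5, seed = 9)
  for (sl in stk) {
    cs <- extract_periosteal(sl)
    for (t in c(500, 700, 900)) {
      am <- isolate_artifacts(sl, cs, t)
      expect_false(any(am$mask & cs$periosteal_mask))
    }
  }
})

test_that("masks and counts match the brute-force oracle exactly", {
  # shipped fixtures
  for (name in c("ring_8x8", "two_components", "exterior_7px",
                 "constant_zero")) {
    fx <- make_fixture(name)
    expect_identical(extract_periosteal(fx)$periosteal_mask,
                     brute_periosteal(fx$pixels), info = name)
    for (t in seq(500, 900, by = 100))
      expect_identical(
        sum(isolate_artifacts(fx, extract_periosteal(fx), t)$mask),
        brute_count(fx$pixels, t), info = paste(name, t))
  }
  # random small images over a mix of HU levels
  set.seed(71)
  for (rep in 1:20) {
    px <- matrix(sample(c(-1000, 0, 300, 600, 950, 1200), 144, replace = TRUE,
                        prob = c(1, 3, 2, 2, 1, 2)), 12, 12)
    img <- slice_image(px)
    expect_identical(extract_periosteal(img)$periosteal_mask,
                     brute_periosteal(px))
    for (t in c(500, 660, 900))
      expect_identical(
        sum(isolate_artifacts(img, extract_periosteal(img), t)$mask),
        brute_count(px, t))
  }
})
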