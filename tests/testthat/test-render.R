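test_that("base image fills air, body, wall and insert with their HU values", {
  ph <- default_qrm_efp(50, body_radius = 11)
  sc <- scan_params(matrix_size = 129, pixel_spacing = 0.2)
  img <- render_base_image(ph, sc)
  cc <- 65  # odd matrix: grid centre falls on a pixel
  expect_equal(img$pixels[cc, cc], 70)          # insert, 50 mg HA
  expect_equal(img$pixels[1, 1], -1000)         # air corner
  # pixel on the +x axis in the middle of the wall annulus
  wall_col <- cc + round((ph$outer_radius - 0.5 * ph$cortical_wall_thickness) /
                           sc$pixel_spacing)
  expect_equal(img$pixels[cc, wall_col], 1120)
  # body between ring and body radius is water (0 HU)
  body_col <- cc + round(10.5 / sc$pixel_spacing)
  expect_equal(img$pixels[cc, body_col], 0)
  # deterministic
  expect_identical(render_base_image(ph, sc)$pixels, img$pixels)
})

test_that("phantom larger than the field of view is a geometry error", {
  ph <- default_qrm_efp(50)  # body radius 20 mm
  expect_error(render_base_image(ph, scan_params(matrix_size = 64,
                                                 pixel_spacing = 0.2)),
               "field of view")
})

test_that("zero electron density adds no streaks", {
  ph <- default_qrm_efp(0, trabecular_rho_e = 0)
  sc <- tiny_scan()
  base <- render_base_image(ph, sc)
  out <- render_streak_artifacts(base, ph, sc, streak_params(seed = 5))
  expect_identical(out$pixels, base$pixels)
  expect_equal(nrow(attr(out, "streaks")), 0)
})

test_that("streak count equals round(gain * I_s)", {
  # mu = 0.2, insert radius 1 cm, rho_e = 2, S = 3: I_s = 6 exp(-0.2) = 4.9124
  ph <- phantom_spec(outer_radius = 11.2, cortical_wall_thickness = 1.2,
                     trabecular_material = material_spec("t", 0, rho_e = 2,
                                                         mu = 0.2))
  sc <- scan_params(matrix_size = 128, pixel_spacing = 0.5, s_per_electron = 3)
  base <- render_base_image(ph, sc)
  out <- render_streak_artifacts(base, ph, sc, streak_params(gain = 10,
                                                             seed = 3))
  st <- attr(out, "streaks")
  expect_equal(nrow(st), 49)                 # round(10 * 4.9124)
  expect_equal(length(unique(st$angle)), 49) # all distinct angles logged
})

test_that("streak rendering is reproducible and exterior-only", {
  ph <- default_qrm_efp(100)
  sc <- tiny_scan()
  base <- render_base_image(ph, sc)
  p <- streak_params(seed = 11)
  a <- render_streak_artifacts(base, ph, sc, p)
  b <- render_streak_artifacts(base, ph, sc, p)
  expect_identical(a$pixels, b$pixels)
  expect_gt(nrow(attr(a, "streaks")), 0)
  # insert interior and ring untouched
  n <- sc$matrix_size
  cc <- (n + 1) / 2
  xs <- (seq_len(n) - cc) * sc$pixel_spacing
  r <- sqrt(outer(xs^2, xs^2, `+`))
  inside <- r <= ph$outer_radius
  expect_identical(a$pixels[inside], base$pixels[inside])
  # something changed outside
  expect_gt(sum(a$pixels != base$pixels), 0)
})

test_that("stacks derive per-slice seeds from the master seed", {
  ph <- default_qrm_efp(50)
  sc <- tiny_scan()
  p <- streak_params(gain = 10)
  s1 <- simulate_stack(ph, sc, p, n_slices = 40, seed = 42)
  expect_length(s1, 40)
  expect_equal(vapply(s1, `[[`, integer(1), "slice_index"), 0:39)
  # rerun with the recorded seed: identical counts and pixels
  s2 <- simulate_stack(ph, sc, p, n_slices = 40, seed = 42)
  expect_identical(lapply(s1, `[[`, "pixels"), lapply(s2, `[[`, "pixels"))
  # a different master seed moves the streaks but shares the base image
  s3 <- simulate_stack(ph, sc, p, n_slices = 2, seed = 43)
  expect_false(identical(s1[[1]]$pixels, s3[[1]]$pixels))
  base <- render_base_image(ph, sc)$pixels
  untouched <- s1[[1]]$pixels == base & s3[[1]]$pixels == base
  expect_identical((s1[[1]]$pixels == s3[[1]]$pixels)[untouched],
                   rep(TRUE, sum(untouched)))
  expect_error(simulate_stack(ph, sc, p, n_slices = 0, seed = 1), ">= 1")
})
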