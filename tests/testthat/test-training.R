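test_that("the training loss is the Frobenius norm of the error matrix", {
  a <- matrix(c(3, 0, 4, 0), 2, 2)
  expect_equal(frobenius_loss(a, matrix(0, 2, 2)), 5)
  expect_equal(frobenius_loss(a, a), 0)
  set.seed(1)
  x <- matrix(stats::rnorm(30), 5, 6); y <- matrix(stats::rnorm(30), 5, 6)
  # brute-force sum-of-squares oracle
  brute <- 0
  for (i in 1:5) for (j in 1:6) brute <- brute + (x[i, j] - y[i, j])^2
  expect_equal(frobenius_loss(x, y), sqrt(brute), tolerance = 1e-12)
  expect_error(frobenius_loss(x, matrix(0, 2, 2)), "shape mismatch")
})

test_that("a delta calibration scene makes the kernel a one-epoch read-off", {
  sc <- matrix(0, 64, 64); sc[33, 33] <- 1
  k <- random_kernel(9, 21)
  shot <- capture(source_image(sc), k, noiseless_exposure())
  est <- estimate_kernel(calibration_pair(source_image(sc), shot),
                         kernel_shape = c(9, 9), epochs = 1)
  obs_crop <- shot$counts[29:37, 29:37]
  expect_equal(est$kernel$grid, obs_crop / sum(obs_crop), tolerance = 1e-12)
})

test_that("noiseless calibration recovers a known kernel", {
  set.seed(31)
  scene <- make_glyph_phantom(c(96, 96), "41")
  Ktrue <- matrix(stats::runif(49), 7, 7); Ktrue <- Ktrue / sum(Ktrue)
  shot <- capture(scene, psf_kernel(Ktrue, 1), noiseless_exposure())
  est <- estimate_kernel(calibration_pair(scene, shot),
                         kernel_shape = c(7, 7), epochs = 150)
  expect_lt(sqrt(mean((est$kernel$grid - Ktrue)^2)), 1e-3)
  expect_true(all(diff(est$trace$loss) <= 1e-12))
  expect_equal(est$trace$epochs, 150)
  expect_gt(utils::tail(est$trace$stability, 1), 0.99)
  expect_true(all(est$kernel$grid >= 0))
  expect_equal(sum(est$kernel$grid), 1, tolerance = 1e-12)
})

test_that("default training runs sixty epochs and records both traces", {
  scene <- make_glyph_phantom(c(64, 64), "8")
  shot <- capture(scene, random_kernel(5, 2), noiseless_exposure())
  est <- estimate_kernel(calibration_pair(scene, shot), kernel_shape = c(5, 5))
  expect_equal(est$trace$epochs, 60)
  expect_length(est$trace$loss, 60)
  expect_length(stability(est$trace), 60)
  expect_error(stability(training_trace(1, 1)), "at least 2")
})

test_that("the estimate ignores the calibration scene's global scale", {
  scene1 <- make_glyph_phantom(c(64, 64), "6")
  k <- random_kernel(7, 12)
  shot1 <- capture(scene1, k, noiseless_exposure())
  scene2 <- source_image(scene1$intensity * 0.4, scene1$pixel_pitch_um)
  shot2 <- capture(scene2, k, noiseless_exposure())
  e1 <- estimate_kernel(calibration_pair(scene1, shot1), c(7, 7), epochs = 40)
  e2 <- estimate_kernel(calibration_pair(scene2, shot2), c(7, 7), epochs = 40)
  expect_lt(sqrt(mean((e1$kernel$grid - e2$kernel$grid)^2)), 1e-6)
})

test_that("recovery degrades gracefully as the photon budget drops", {
  scene <- make_glyph_phantom(c(64, 64), "92")
  Ktrue <- random_kernel(7, 33)
  rmse_at_budget <- function(budget) {
    vals <- sapply(1:5, function(s) {
      shot <- capture(scene, Ktrue,
                      exposure_settings(photons_per_pixel_per_ms = budget,
                                        seed = s, bin_factor = 1))
      est <- suppressWarnings(
        estimate_kernel(calibration_pair(scene, shot), c(7, 7), epochs = 60))
      sqrt(mean((est$kernel$grid - Ktrue$grid)^2))
    })
    mean(vals)
  }
  expect_gte(rmse_at_budget(5), rmse_at_budget(50))
})

test_that("a plain-system capture estimates to a near-delta kernel", {
  scene <- make_glyph_phantom(c(96, 96), "239")
  shot <- capture(scene, delta_kernel(1),
                  exposure_settings(t_cap_ms = 100, seed = 5, bin_factor = 1))
  est <- suppressWarnings(
    estimate_kernel(calibration_pair(scene, shot), c(9, 9), epochs = 60))
  ctr <- est$kernel$center
  near <- est$kernel$grid[(ctr[1] - 1):(ctr[1] + 1), (ctr[2] - 1):(ctr[2] + 1)]
  expect_gt(sum(near), 0.9)
})

test_that("noisier calibrations train less stably", {
  scene <- make_glyph_phantom(c(96, 96), "239")
  k <- random_kernel(9, 3)
  late_stability <- function(t_cap) {
    vals <- sapply(1:3, function(s) {
      shot <- capture(scene, k, exposure_settings(t_cap_ms = t_cap, seed = s,
                                                  bin_factor = 1))
      est <- suppressWarnings(
        estimate_kernel(calibration_pair(scene, shot), c(9, 9), epochs = 40))
      mean(utils::tail(est$trace$stability, 10))
    })
    mean(vals)
  }
  expect_lt(late_stability(20), late_stability(100) + 1e-9)
})

test_that("calibration pairs validate shapes and kernel shape parity", {
  scene <- make_glyph_phantom(c(64, 64), "1")
  shot <- capture(scene, random_kernel(5, 1), noiseless_exposure(bin = 2))
  expect_silent(cp <- calibration_pair(scene, shot))
  expect_error(estimate_kernel(cp, kernel_shape = c(8, 8)), "odd")
  bad <- capture(make_glyph_phantom(c(32, 32), "1"), random_kernel(5, 1),
                 noiseless_exposure())
  expect_error(calibration_pair(scene, bad), "match")
})
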