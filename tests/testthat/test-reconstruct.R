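test_that("Richardson-Lucy with a delta kernel is the identity", {
  ph <- make_glyph_phantom(c(48, 48), "2")
  for (iters in c(1, 7, 30)) {
    r <- richardson_lucy(ph$intensity, delta_kernel(3), iterations = iters)
    expect_equal(r$image, ph$intensity, tolerance = 1e-12)
  }
  expect_error(richardson_lucy(matrix(0, 8, 8), delta_kernel(1)), "all-zero")
  expect_error(richardson_lucy(matrix(1, 8, 8), delta_kernel(1),
                               iterations = 0), "iterations")
})

test_that("RL with the true kernel converges on every phantom family", {
  sys <- std_system(); spec <- std_spectrum()
  fams <- phantom_families()
  for (nm in names(fams)) {
    ph <- fams[[nm]]
    gs <- if (ph$pixel_pitch_um < 1) c(41, 41) else c(25, 25)
    k <- build_psf(metasurface(300, "grating_1d"), sys, spec,
                   grid_shape = gs,
                   pixel_pitch_um = ph$pixel_pitch_um)
    shot <- capture(ph, k, noiseless_exposure())
    r1 <- richardson_lucy(shot, k, 1, stop_tol = 0)
    r30 <- richardson_lucy(shot, k, 30, stop_tol = 0)
    e1 <- scaled_rmse(r1$image, ph$intensity)
    e30 <- scaled_rmse(r30$image, ph$intensity)
    expect_lt(e30, e1)
  }
})

test_that("RL conserves interior flux and commutes with rescaling", {
  ph <- make_glyph_phantom(c(64, 64), "8")
  k <- random_kernel(7, 5)
  shot <- capture(ph, k, noiseless_exposure())
  r <- richardson_lucy(shot, k, 25, stop_tol = 0)
  # crop covering the glyph plus a kernel-radius margin
  crop <- 5:59
  expect_lt(abs(sum(r$image[crop, crop]) / sum(shot$counts[crop, crop]) - 1),
            1e-3)
  expect_lt(abs(sum(r$image) / sum(shot$counts) - 1), 1e-3)
  r2 <- richardson_lucy(shot$counts * 7.5, k, 25, stop_tol = 0)
  expect_equal(r2$image, r$image * 7.5, tolerance = 1e-9)
})

test_that("baseline filters reduce to the identity at degenerate settings", {
  set.seed(4)
  img <- matrix(stats::runif(32 * 32), 32, 32)
  g0 <- baseline_filter(img, "gaussian", list(sd = 0))
  expect_equal(g0$image, img, tolerance = 1e-9)
  lp <- baseline_filter(img, "lowpass", list(cutoff = 0.5))
  expect_equal(lp$image, img, tolerance = 1e-9)
  expect_error(baseline_filter(img, "bilateral"), "valid methods")
})

test_that("the median filter removes isolated salt-and-pepper outliers", {
  img <- matrix(0.5, 32, 32)
  set.seed(6)
  salt <- sample(32 * 32, 20)
  pepper <- setdiff(sample(32 * 32, 20), salt)
  img[salt] <- 1; img[pepper] <- 0
  # keep outliers isolated: drop any that touch another outlier
  bad <- c(salt, pepper)
  coords <- cbind((bad - 1) %% 32 + 1, (bad - 1) %/% 32 + 1)
  iso <- sapply(seq_along(bad), function(i) {
    d <- pmax(abs(coords[, 1] - coords[i, 1]), abs(coords[, 2] - coords[i, 2]))
    sum(d <= 1) == 1
  })
  img[bad[!iso]] <- 0.5
  med <- baseline_filter(img, "median", list(window = 3))
  expect_equal(med$image, matrix(0.5, 32, 32), tolerance = 1e-12)
})

test_that("wavelet shrinkage denoises a smooth scene", {
  set.seed(8)
  clean <- outer(seq(0, 1, length.out = 64), seq(0, 1, length.out = 64),
                 function(x, y) 0.5 + 0.3 * sin(2 * pi * x) * cos(2 * pi * y))
  noisy <- clean + matrix(stats::rnorm(64 * 64, sd = 0.05), 64, 64)
  for (m in c("wavelet_soft", "wavelet_hard")) {
    den <- baseline_filter(noisy, m)
    expect_lt(mean((den$image - clean)^2), mean((noisy - clean)^2))
  }
})

test_that("Laplacian sharpening steepens edges deterministically", {
  img <- matrix(0.2, 32, 32); img[, 17:32] <- 0.8
  sh <- baseline_filter(img, "laplacian_sharpen")
  expect_gt(max(sh$image[, 17]) - min(sh$image[, 16]),
            max(img[, 17]) - min(img[, 16]))
  expect_identical(sh$image, baseline_filter(img, "laplacian_sharpen")$image)
})

test_that("the decoding pipeline upsamples binned shots and reduces error", {
  sys <- std_system(); spec <- std_spectrum()
  ph <- make_glyph_phantom(c(96, 96), "239")
  k <- build_psf(metasurface(300, "grating_1d"), sys, spec,
                 grid_shape = c(25, 25))
  shot <- capture(ph, k, exposure_settings(t_cap_ms = 100, seed = 3,
                                           bin_factor = 2))
  calib_shot <- capture(ph, k, exposure_settings(t_cap_ms = 100, seed = 9,
                                                 bin_factor = 2))
  est <- estimate_kernel(calibration_pair(ph, calib_shot),
                         kernel_shape = c(25, 25), epochs = 40)
  rec <- reconstruct_pipeline(shot, est, iterations = 30)
  expect_equal(dim(rec$image), dim(ph$intensity))
  shot_up <- upsample_bilinear_oracle(shot$counts, 2)
  expect_lt(scaled_rmse(rec$image, ph$intensity),
            scaled_rmse(shot_up, ph$intensity))
})

test_that("a glyph-trained decoder transfers to other sample families", {
  sys <- std_system(); spec <- std_spectrum()
  k <- build_psf(metasurface(300, "grating_1d"), sys, spec,
                 grid_shape = c(25, 25))
  calib <- make_glyph_phantom(c(96, 96), "239")
  calib_shot <- capture(calib, k, exposure_settings(t_cap_ms = 100, seed = 1,
                                                    bin_factor = 1))
  est <- estimate_kernel(calibration_pair(calib, calib_shot),
                         kernel_shape = c(25, 25), epochs = 40)
  for (ph in list(make_fiber_phantom(c(96, 96), 6, seed = 4),
                  make_two_region_phantom(c(96, 96), seed = 4))) {
    shot <- capture(ph, k, exposure_settings(t_cap_ms = 100, seed = 7,
                                             bin_factor = 1))
    rec <- reconstruct_pipeline(shot, est, iterations = 30)
    expect_lt(scaled_rmse(rec$image, ph$intensity),
              scaled_rmse(shot$counts, ph$intensity))
  }
})

test_that("an RL decoder with a delta kernel leaves plain shots unchanged", {
  ph <- make_two_region_phantom(c(96, 96), seed = 2)
  shot <- capture(ph, delta_kernel(1), exposure_settings(seed = 4,
                                                         bin_factor = 1))
  rec <- richardson_lucy(shot, delta_kernel(3), iterations = 20)
  expect_equal(rec$image, shot$counts, tolerance = 1e-12)
  reg_a <- region_spec(ph$regions$a, "a")
  reg_b <- region_spec(ph$regions$b, "b")
  blank <- region_spec(ph$regions$blank, "blank")
  expect_equal(intensity_ratio(rec$image, reg_a, blank),
               intensity_ratio(shot$counts, reg_a, blank), tolerance = 1e-9)
  expect_equal(cnr(rec$image, reg_a, reg_b, blank),
               cnr(shot$counts, reg_a, reg_b, blank), tolerance = 1e-9)
})
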