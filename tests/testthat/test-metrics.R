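test_that("identical image and reference pin the SNR curve at the cap", {
  ph <- make_glyph_phantom(c(64, 64), "5")$intensity
  cv <- snr_curve(ph, ph, pixel_pitch_um = 1)
  expect_true(all(cv$snr_db == 80))
  expect_true(all(diff(cv$freq_bins) > 0))
  expect_error(snr_curve(matrix(0, 8, 8), matrix(0, 8, 8)), "zero power")
})

test_that("white-noise power per bin matches its variance (Parseval)", {
  set.seed(10)
  ref <- outer(seq(0, 1, length.out = 256), seq(0, 1, length.out = 256),
               function(x, y) 1 + 0.3 * sin(2 * pi * 3 * x) +
                 0.2 * cos(2 * pi * 5 * y))
  sd_true <- 0.07
  img <- ref + matrix(stats::rnorm(256^2, sd = sd_true), 256, 256)
  cv <- snr_curve(img, ref, pixel_pitch_um = 1, n_bins = 24)
  expect_equal(cv$gain, 1, tolerance = 1e-3)
  # skip the lowest bins, where reference mismatch leakage can contribute
  sel <- cv$freq_bins > 0.1
  expect_lt(abs(mean(cv$p_noise[sel]) / sd_true^2 - 1), 0.1)
})

test_that("SNR curves are invariant to a common rescaling", {
  set.seed(11)
  ref <- matrix(stats::runif(64 * 64, 0.5, 1), 64, 64)
  img <- ref + matrix(stats::rnorm(64 * 64, sd = 0.05), 64, 64)
  c1 <- snr_curve(img, ref, pixel_pitch_um = 2)
  c2 <- snr_curve(img * 13.7, ref * 13.7, pixel_pitch_um = 2)
  expect_equal(c1$snr_db, c2$snr_db, tolerance = 1e-9)
})

test_that("more noise means lower SNR in expectation", {
  set.seed(12)
  ref <- outer(seq_len(96), seq_len(96),
               function(x, y) 1 + 0.2 * sin(x / 5) * cos(y / 7))
  wins <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    n1 <- matrix(stats::rnorm(96^2, sd = 0.02), 96, 96)
    n2 <- matrix(stats::rnorm(96^2, sd = 0.10), 96, 96)
    c1 <- snr_curve(ref + n1, ref, pixel_pitch_um = 1)
    c2 <- snr_curve(ref + n2, ref, pixel_pitch_um = 1)
    # compare raw band powers (the dB offset is self-normalized away)
    if (mean(c1$p_noise) < mean(c2$p_noise)) wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("intensity ratios follow their closed forms", {
  ph <- make_fringe_phantom(c(64, 128), pitch_um = 3, n_lines = 7,
                            depth = 0.5, pixel_pitch_um = 0.5)
  stripe <- region_spec(ph$regions$stripe, "stripe")
  blank <- region_spec(ph$regions$blank, "blank")
  expect_equal(intensity_ratio(ph$intensity, stripe, blank), 0.75)
  # monotone in depth
  ratios <- sapply(c(0.2, 0.4, 0.6, 0.8), function(d) {
    p <- make_fringe_phantom(c(64, 128), 3, 7, depth = d, pixel_pitch_um = 0.5)
    intensity_ratio(p$intensity, region_spec(p$regions$stripe, "s"),
                    region_spec(p$regions$blank, "b"))
  })
  expect_true(all(diff(ratios) < 0))
  # identical statistics in both regions
  set.seed(13)
  img <- matrix(stats::runif(64 * 64, 0.4, 0.6), 64, 64)
  m1 <- matrix(FALSE, 64, 64); m1[, 1:20] <- TRUE
  m2 <- matrix(FALSE, 64, 64); m2[, 41:60] <- TRUE
  r <- intensity_ratio(img, region_spec(m1, "a"), region_spec(m2, "b"))
  expect_equal(r, 1, tolerance = 0.02)
  expect_error(region_spec(matrix(FALSE, 4, 4)), "empty")
  expect_error(intensity_ratio(img, region_spec(m1, "a"),
                               region_spec(m1, "a")), "overlap")
})

test_that("contrast-to-noise ratios follow the contrast-ratio convention", {
  img <- matrix(1, 32, 96)
  img[, 1:24] <- 0.5; img[, 33:56] <- 0.75
  a <- region_spec(cbind(matrix(TRUE, 32, 24), matrix(FALSE, 32, 72)), "a")
  bm <- matrix(FALSE, 32, 96); bm[, 33:56] <- TRUE
  b <- region_spec(bm, "b")
  blm <- matrix(FALSE, 32, 96); blm[, 65:96] <- TRUE
  blank <- region_spec(blm, "blank")
  expect_equal(cnr(img, a, b, blank), 2)
  expect_equal(cnr(img, a, b, blank) * cnr(img, b, a, blank), 1,
               tolerance = 1e-12)
  img2 <- img; img2[, 33:56] <- 0.5
  expect_equal(cnr(img2, a, b, blank), 1)
  img3 <- img; img3[, 33:56] <- 1
  expect_error(cnr(img3, a, b, blank), "zero absorption contrast")
})

test_that("Fourier spectra obey the DFT identities", {
  flat <- matrix(3, 32, 32)
  sp <- fourier_spectrum_2d(flat)
  expect_equal(sp[17, 17], 3 * 32 * 32)
  expect_equal(sum(sp) - sp[17, 17], 0, tolerance = 1e-9)
  # pure horizontal sinusoid: two symmetric peaks at +-k
  k <- 5
  x <- matrix(rep(cos(2 * pi * k * (0:31) / 32), times = 32), 32, 32)
  sp2 <- fourier_spectrum_2d(x)  # varies along rows
  peaks <- order(sp2, decreasing = TRUE)[1:2]
  rc <- cbind((peaks - 1) %% 32 + 1, (peaks - 1) %/% 32 + 1)
  expect_setequal(rc[, 1], c(17 - k, 17 + k))
  expect_true(all(rc[, 2] == 17))
  # Parseval
  set.seed(14)
  y <- matrix(stats::runif(24 * 24), 24, 24)
  expect_equal(sum(fourier_spectrum_2d(y)^2), length(y) * sum(y^2),
               tolerance = 1e-6)
})

test_that("section profiles sample the scene as generated", {
  ph <- make_fringe_phantom(c(64, 128), pitch_um = 4, n_lines = 5,
                            depth = 0.6, pixel_pitch_um = 1)
  prof <- section_profile(ph$intensity, c(32, 1), c(32, 128), width = 1)
  expect_equal(prof, ph$intensity[32, ], tolerance = 1e-12)
  expect_equal(count_profile_minima(prof), 5L)
  uni <- section_profile(matrix(0.7, 32, 32), c(5, 2), c(28, 30), width = 3)
  expect_true(all(abs(uni - 0.7) < 1e-12))
  expect_error(section_profile(ph$intensity, c(10, 10), c(10, 10)),
               "degenerate")
})

test_that("prominence filtering ignores shallow ripple minima", {
  x <- 1 - 0.5 * (abs(seq(-3, 3, length.out = 61)) < 0.5)
  expect_equal(count_profile_minima(x), 1L)
  ripple <- x + 0.004 * sin(seq(0, 40, length.out = 61))
  expect_equal(count_profile_minima(ripple, min_prominence = 0.05), 1L)
  expect_equal(count_profile_minima(rep(1, 10)), 0L)
})
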