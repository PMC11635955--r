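test_that("critical angle follows the arcsine law", {
  expect_equal(critical_angle(1), 90)
  expect_equal(critical_angle(sqrt(2)), 45)
  # numeric arcsine oracle for Ce:YAG
  expect_equal(critical_angle(1.82), asin(1 / 1.82) * 180 / pi)
  expect_equal(round(critical_angle(1.82), 1), 33.3)
  expect_error(critical_angle(0.9), "n_scint")
})

test_that("escape-cone fraction covers the limits and is monotone", {
  expect_equal(escape_fraction(1), 0.5)
  expect_lt(escape_fraction(1e3), 1e-6)
  ns <- seq(1.01, 4, by = 0.01)
  expect_true(all(diff(escape_fraction(ns)) < 0))
  expect_error(escape_fraction(0.5))
})

test_that("exit sine reproduces normal incidence, TIR and first-order cases", {
  expect_equal(diffraction_exit_sine(0, 550, 300, 0, 1.82), 0)
  # zero order vanishes from the pattern at 40 degrees in a high-index medium
  expect_gt(abs(diffraction_exit_sine(40, 550, 300, 0, 1.82)), 1)
  # first order survives at steep incidence: 1.82 sin(70) - 550/300
  s <- diffraction_exit_sine(70, 550, 300, 1, 1.82)
  expect_equal(s, 1.82 * sin(70 * pi / 180) - 550 / 300)
  expect_equal(round(s, 3), -0.123)
  expect_lt(abs(s), 1)
  # zero order is independent of the period
  expect_equal(diffraction_exit_sine(25, 420, 200, 0, 1.82),
               diffraction_exit_sine(25, 420, 900, 0, 1.82))
  expect_error(diffraction_exit_sine(10, 550, -1, 1))
})

test_that("order tables match the admission structure of the period presets", {
  sys <- std_system(); spec <- std_spectrum()
  crit <- critical_angle(sys$n_scint)

  tab3 <- order_table(metasurface(300, "grating_1d"), sys, spec,
                      theta_grid = 40:70)
  adm3 <- tab3[tab3$in_acceptance, ]
  expect_gt(nrow(adm3), 0)
  expect_true(all(abs(adm3$order) == 1))

  tab4 <- order_table(metasurface(400, "grating_1d"), sys, spec)
  expect_true(any(tab4$propagating & abs(tab4$order) == 2))

  tab2 <- order_table(metasurface(200, "grating_1d"), sys, spec)
  expect_false(any(tab2$in_acceptance & tab2$theta_deg > crit))

  expect_error(order_table(metasurface(300, "grating_1d"), sys,
                           structure(list(wavelength_nm = numeric(0),
                                          weight = numeric(0)),
                                     class = "emission_spectrum")),
               "nonempty")
})

test_that("plain-interface admission equals the Snell/TIR closed form", {
  sys <- std_system(acceptance_half_angle_deg = 90)
  spec <- emission_spectrum(550)
  tab <- order_table(metasurface(geometry = "none"), sys, spec,
                     theta_grid = seq(0, 89, by = 1))
  expect_true(all(tab$order == 0))
  crit <- critical_angle(sys$n_scint)
  expect_equal(tab$in_acceptance, tab$theta_deg < crit)
  expect_equal(tab$propagating, sys$n_scint * sin(tab$theta_deg * pi / 180) < 1)
})

test_that("identity configuration returns the system kernel itself", {
  sk <- psf_kernel(matrix(c(0, 1, 0, 1, 4, 1, 0, 1, 0), 3, 3), 1)
  sys <- std_system(system_kernel = sk)
  k <- build_psf(metasurface(geometry = "none"), sys, emission_spectrum(550),
                 theta_grid = 0, theta_weighting = "normal",
                 grid_shape = c(9, 9))
  ctr <- k$center
  expect_equal(k$grid[(ctr[1] - 1):(ctr[1] + 1), (ctr[2] - 1):(ctr[2] + 1)],
               sk$grid, tolerance = 1e-12)
  expect_equal(sum(k$grid), 1, tolerance = 1e-12)
  expect_equal(k$collection_gain, 1)
})

test_that("a single first-order pair produces two symmetric spikes", {
  # lambda/xi = 0.5 -> exit at 30 deg; distance chosen so d = 3 px exactly
  L <- 3 / tan(asin(0.5))
  sys <- optical_system(n_scint = 1.82, acceptance_half_angle_deg = 40,
                        propagation_distance_um = L)
  meta <- metasurface(1000, "grating_1d", efficiency_model = "user_table",
                      order_range = 1,
                      efficiency_table = c("-1" = 1, "0" = 0, "1" = 1))
  k <- build_psf(meta, sys, emission_spectrum(500), theta_grid = 0,
                 theta_weighting = "normal", grid_shape = c(9, 9),
                 pixel_pitch_um = 1)
  expected <- matrix(0, 9, 9)
  expected[5, 2] <- 0.5; expected[5, 8] <- 0.5
  expect_equal(k$grid, expected, tolerance = 1e-12)
})

test_that("built kernels are normalized, mirror-symmetric and fit their grid", {
  sys <- std_system(); spec <- std_spectrum()
  k <- build_psf(metasurface(300, "grating_1d"), sys, spec)
  expect_equal(sum(k$grid), 1, tolerance = 1e-12)
  expect_true(all(k$grid >= 0))
  # m -> -m reversal symmetry: the kernel mirrors about its center
  expect_equal(k$grid, k$grid[nrow(k$grid):1, ncol(k$grid):1],
               tolerance = 1e-12)
  expect_error(build_psf(metasurface(300, "grating_1d"), sys, spec,
                         grid_shape = c(5, 5)),
               "grid_shape of at least")
})

test_that("metasurfaces that bend trapped light earn a collection gain", {
  sys <- std_system(); spec <- std_spectrum()
  k_none <- build_psf(metasurface(geometry = "none"), sys, spec)
  k_tex <- build_psf(metasurface(300, "grating_1d"), sys, spec)
  k_reg <- build_psf(metasurface(500, "isotropic_2d"), sys, spec)
  expect_equal(k_none$collection_gain, 1, tolerance = 1e-12)
  expect_gt(k_tex$collection_gain, 1)
  expect_gt(k_reg$collection_gain, 1)
})

test_that("constructors validate their invariants", {
  expect_error(optical_system(n_scint = 0.8), "refractive index")
  expect_error(optical_system(acceptance_half_angle_deg = 0), "acceptance")
  expect_error(metasurface(geometry = "grating_1d"), "period_nm")
  expect_error(emission_spectrum(c(500, -1)), "positive")
  expect_error(psf_kernel(matrix(-1, 3, 3)), "nonnegative")
  expect_error(psf_kernel(matrix(1, 3, 3), center = c(5, 1)), "center")
})
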