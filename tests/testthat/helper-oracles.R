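# Independent oracles and shared fixtures for the test suite.
# The convolution oracle below is a plain nested loop with symmetric
# boundary reflection; it never calls the package's FFT path.

direct_conv2 <- function(img, kern, center = NULL) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(kern); kc <- ncol(kern)
  if (is.null(center)) center <- c((kr + 1) %/% 2 + (kr %% 2 == 0),
                                   (kc + 1) %/% 2 + (kc %% 2 == 0))
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, nr, nc)
  for (x in seq_len(nr)) for (y in seq_len(nc)) {
    s <- 0
    for (i in seq_len(kr)) for (j in seq_len(kc)) {
      s <- s + kern[i, j] * img[reflect(x - (i - center[1]), nr),
                                reflect(y - (j - center[2]), nc)]
    }
    out[x, y] <- s
  }
  out
}

std_system <- function(...) optical_system(...)
std_spectrum <- function() emission_spectrum()

random_kernel <- function(size, seed) {
  set.seed(seed)
  k <- matrix(stats::runif(size^2), size, size)
  psf_kernel(k / sum(k), 1)
}

noiseless_exposure <- function(bin = 1L, t_cap = 20)
  exposure_settings(t_cap_ms = t_cap, bin_factor = bin, noiseless = TRUE)

# RMSE between a reconstruction and the truth after least-squares scale
# matching (reconstructions carry the photon-count scale).
scaled_rmse <- function(img, truth) {
  g <- sum(img * truth) / sum(img^2)
  sqrt(mean((g * img - truth)^2))
}

# nearest-neighbour upsampling, as a plain reference rescaler
upsample_bilinear_oracle <- function(x, f) kronecker(x, matrix(1, f, f))

# the four phantom families at a small common size
phantom_families <- function(size = c(96, 96), seed = 5) {
  list(fringe = make_fringe_phantom(size, pitch_um = 3, n_lines = 7,
                                    pixel_pitch_um = 0.5),
       glyph = make_glyph_phantom(size, "239"),
       two_region = make_two_region_phantom(size, seed = seed),
       fiber = make_fiber_phantom(size, n_fibers = 6, seed = seed))
}
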