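# Incoherent image capture: the scene is convolved with the system PSF,
# scaled by the photon budget, subjected to Poisson shot noise and Gaussian
# read noise, and binned onto the detector grid.

#' Exposure and detector settings
#'
#' @param t_cap_ms capture time in milliseconds
#' @param photons_per_pixel_per_ms blank-field photon budget per (source)
#'   pixel per millisecond. The default of 50 makes 20 ms captures visibly
#'   shot-noise limited while 100 ms captures are close to clean.
#' @param read_noise_sd additive Gaussian detector noise (counts)
#' @param bin_factor integer detector downsampling factor (counts are summed
#'   over `bin_factor x bin_factor` blocks)
#' @param seed integer RNG seed (Mersenne-Twister)
#' @param noiseless bypass both noise terms (oracle mode)
#' @return an object of class `exposure_settings`
#' @export
exposure_settings <- function(t_cap_ms = 20, photons_per_pixel_per_ms = 50,
                              read_noise_sd = 2, bin_factor = 2L,
                              seed = 1L, noiseless = FALSE) {
  if (t_cap_ms <= 0 || photons_per_pixel_per_ms <= 0)
    stop("t_cap_ms and photons_per_pixel_per_ms must be positive")
  if (read_noise_sd < 0) stop("read_noise_sd must be nonnegative")
  if (bin_factor < 1) stop("bin_factor must be >= 1")
  structure(list(t_cap_ms = t_cap_ms,
                 photons_per_pixel_per_ms = photons_per_pixel_per_ms,
                 read_noise_sd = read_noise_sd,
                 bin_factor = as.integer(bin_factor),
                 seed = as.integer(seed),
                 noiseless = isTRUE(noiseless),
                 rng_kind = "Mersenne-Twister"),
            class = "exposure_settings")
}

#' Captured detector frame
#'
#' Constructed by [capture()]; rarely needed directly.
#'
#' @param counts nonnegative numeric matrix of detector counts
#' @param settings the [exposure_settings()] used
#' @param kernel_id provenance string for the kernel
#' @param pixel_pitch_um detector pixel pitch (source pitch times bin factor)
#' @export
captured_image <- function(counts, settings, kernel_id = NA_character_,
                           pixel_pitch_um = NA_real_) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  structure(list(counts = counts, settings = settings, kernel_id = kernel_id,
                 pixel_pitch_um = pixel_pitch_um),
            class = "captured_image")
}

#' Simulate incoherent capture of a scene through the optical encoder
#'
#' Computes `BIN(POISSON(t_cap * flux * gain * (I %conv% K)) + N(0,
#' read_noise))`, clipped at zero, where `gain` is the kernel's light
#' collection efficiency relative to the plain interface (see
#' [build_psf()]); the photon budget of the settings refers to the
#' blank-field rate through the plain system. The convolution is linear and
#' FFT-accelerated with reflective boundary padding; the draw is fully
#' determined by the settings seed.
#'
#' @param src a [source_image()] (or plain matrix in `[0, 1]`)
#' @param kernel a [psf_kernel()], normalized
#' @param exposure an [exposure_settings()]
#' @return a [captured_image()]
#' @export
capture <- function(src, kernel, exposure = exposure_settings()) {
  stopifnot(inherits(kernel, "psf_kernel"),
            inherits(exposure, "exposure_settings"))
  img <- image_data(src)
  if (nrow(kernel$grid) > nrow(img) || ncol(kernel$grid) > ncol(img))
    stop("kernel larger than image")
  sp <- pitch_of(src)
  if (!is.null(sp) && !is.na(kernel$pixel_pitch_um) &&
      abs(sp - kernel$pixel_pitch_um) > 1e-9 * max(sp, kernel$pixel_pitch_um))
    warning("source and kernel pixel pitches differ (",
            sp, " vs ", kernel$pixel_pitch_um, " um)")
  gain <- if (is.null(kernel$collection_gain)) 1 else kernel$collection_gain
  flux <- exposure$t_cap_ms * exposure$photons_per_pixel_per_ms * gain
  expected <- flux * conv2_reflect(img, kernel$grid, kernel$center)
  expected[expected < 0] <- 0
  if (exposure$noiseless) {
    counts <- bin_sum(expected, exposure$bin_factor)
  } else {
    set.seed(exposure$seed, kind = exposure$rng_kind)
    shot <- matrix(stats::rpois(length(expected), lambda = expected),
                   nrow(expected), ncol(expected))
    if (exposure$read_noise_sd > 0)
      shot <- shot + matrix(stats::rnorm(length(shot),
                                         sd = exposure$read_noise_sd),
                            nrow(shot), ncol(shot))
    counts <- bin_sum(shot, exposure$bin_factor)
    counts[counts < 0] <- 0
  }
  kernel_id <- fnv1a_hash(list(dim(kernel$grid), kernel$center,
                               signif(kernel$grid, 8)))
  pitch <- pitch_of(src, default = kernel$pixel_pitch_um)
  captured_image(counts, exposure, kernel_id,
                 pixel_pitch_um = if (is.null(pitch)) NA_real_ else
                   pitch * exposure$bin_factor)
}

#' Long-exposure reference capture
#'
#' Reference frame taken through the plain system at a long capture time
#' (>= 100 ms), used as the ground-truth stand-in for SNR evaluation.
#'
#' @param src a [source_image()]
#' @param kernel_none the plain-system [psf_kernel()]
#' @param exposure an [exposure_settings()] with `t_cap_ms >= 100`
#' @export
long_exposure_reference <- function(src, kernel_none,
                                    exposure = exposure_settings(t_cap_ms = 100)) {
  if (exposure$t_cap_ms < 100)
    stop("a long-exposure reference requires t_cap_ms >= 100")
  capture(src, kernel_none, exposure)
}
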