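# Toy parallel-beam tomography loop: discrete Radon projection of an
# attenuation map, per-projection degradation through the capture model
# (1D restriction of the kernel), per-projection Richardson-Lucy decoding,
# and ramp-filtered back-projection.

#' Sinogram container
#'
#' @param data angles x detector-bins matrix of line integrals
#' @param angles_deg projection angles, strictly increasing in `[0, 180)`
#' @param detector_pitch_um detector bin spacing in micrometres
#' @export
sinogram <- function(data, angles_deg, detector_pitch_um = 1) {
  data <- as.matrix(data)
  if (nrow(data) != length(angles_deg))
    stop("sinogram rows must equal the number of angles")
  if (any(diff(angles_deg) <= 0) || any(angles_deg < 0) || any(angles_deg >= 180))
    stop("angles must be strictly increasing in [0, 180)")
  structure(list(data = data, angles_deg = angles_deg,
                 detector_pitch_um = detector_pitch_um),
            class = "sinogram")
}

#' Parallel-beam projection (discrete Radon transform)
#'
#' Line integrals of an attenuation map along parallel rays per angle, via
#' bilinear sampling on a rotated grid. Pass an attenuation map (for the
#' transmittance phantoms of this package, `1 - intensity`); values are used
#' as-is.
#'
#' @param phantom square numeric matrix (or [source_image()], whose intensity
#'   is then used directly as the attenuation map)
#' @param angles_deg projection angles in `[0, 180)`
#' @return a [sinogram()]; projections carry units of value times
#'   micrometres, so each row sums to the phantom mass times the pitch
#' @export
project <- function(phantom, angles_deg = seq(0, 179, by = 1)) {
  pitch <- pitch_of(phantom, 1)
  f <- image_data(phantom)
  if (nrow(f) != ncol(f)) stop("phantom must be square")
  if (any(angles_deg < 0 | angles_deg >= 180)) stop("angles must lie in [0, 180)")
  n <- nrow(f)
  ctr <- (n + 1) / 2
  s <- seq_len(n) - ctr
  tt <- s
  grid <- expand.grid(s = s, t = tt)
  sino <- matrix(0, length(angles_deg), n)
  for (a in seq_along(angles_deg)) {
    th <- angles_deg[a] * pi / 180
    sx <- grid$s * cos(th) - grid$t * sin(th) + ctr
    sy <- grid$s * sin(th) + grid$t * cos(th) + ctr
    vals <- matrix(bilinear_interp(f, sx, sy), n, n)
    # detector index is s (rows of `vals`), integration along t (columns)
    sino[a, ] <- rowSums(vals) * pitch
  }
  sinogram(sino, angles_deg, detector_pitch_um = pitch)
}

# 1D restriction of a PSF: the kernel's central row, renormalized.
kernel_row_profile <- function(kernel) {
  prof <- kernel$grid[kernel$center[1], ]
  if (sum(prof) <= 0)
    stop("kernel's central row carries no weight; cannot restrict to 1D")
  list(profile = prof / sum(prof), center = kernel$center[2])
}

conv1d_reflect <- function(x, h, center) {
  m <- matrix(x, nrow = 1)
  k <- matrix(h, nrow = 1)
  as.vector(conv2_reflect(m, k, center = c(1, center)))
}

#' Degrade sinogram projections through the capture model
#'
#' Each projection row is convolved with the kernel's central-row profile
#' (the 1D restriction of the optical kernel), then subjected to Poisson
#' shot noise and Gaussian read noise at the given exposure, with a child
#' seed per row. Counts are returned rescaled to the sinogram's original
#' units so geometry is preserved.
#'
#' @param sino a [sinogram()]
#' @param kernel a [psf_kernel()]
#' @param exposure an [exposure_settings()] (`bin_factor` is ignored here)
#' @return a degraded [sinogram()]
#' @export
degrade_projections <- function(sino, kernel, exposure = exposure_settings()) {
  stopifnot(inherits(sino, "sinogram"), inherits(kernel, "psf_kernel"))
  rp <- kernel_row_profile(kernel)
  gain <- if (is.null(kernel$collection_gain)) 1 else kernel$collection_gain
  flux <- exposure$t_cap_ms * exposure$photons_per_pixel_per_ms * gain
  out <- sino$data
  for (i in seq_len(nrow(out))) {
    blurred <- conv1d_reflect(sino$data[i, ], rp$profile, rp$center)
    if (exposure$noiseless) {
      out[i, ] <- blurred
    } else {
      set.seed(split_seed(exposure$seed, i), kind = exposure$rng_kind)
      counts <- stats::rpois(length(blurred), lambda = flux * pmax(blurred, 0))
      if (exposure$read_noise_sd > 0)
        counts <- counts + stats::rnorm(length(counts),
                                        sd = exposure$read_noise_sd)
      out[i, ] <- pmax(counts, 0) / flux
    }
  }
  sinogram(out, sino$angles_deg, sino$detector_pitch_um)
}

#' Decode sinogram projections by per-row Richardson-Lucy deconvolution
#'
#' @param sino a degraded [sinogram()]
#' @param kernel the [psf_kernel()] whose 1D central-row restriction blurred
#'   the projections
#' @param iterations Richardson-Lucy iterations per projection
#' @return a decoded [sinogram()]
#' @export
decode_projections <- function(sino, kernel, iterations = 30L) {
  stopifnot(inherits(sino, "sinogram"), inherits(kernel, "psf_kernel"))
  rp <- kernel_row_profile(kernel)
  eps <- 1e-12
  out <- sino$data
  for (i in seq_len(nrow(out))) {
    S <- pmax(sino$data[i, ], 0)
    if (all(S == 0)) { out[i, ] <- S; next }
    x <- rep(mean(S), length(S))
    hrev_center <- length(rp$profile) + 1 - rp$center
    hrev <- rev(rp$profile)
    for (it in seq_len(iterations)) {
      denom <- conv1d_reflect(x, rp$profile, rp$center)
      ratio <- S / pmax(denom, eps)
      x <- x * conv1d_reflect(ratio, hrev, hrev_center)
    }
    out[i, ] <- x
  }
  sinogram(out, sino$angles_deg, sino$detector_pitch_um)
}

#' Filtered back-projection reconstruction
#'
#' Ramp-filtered back-projection on the phantom grid: each projection is
#' zero-padded, filtered in the frequency domain (`ramp` or `shepp-logan`
#' window), back-projected with linear interpolation and scaled by
#' `pi / (2 n_angles)`.
#'
#' @param sino a [sinogram()] with at least 8 angles
#' @param filter `"ramp"` or `"shepp-logan"`
#' @param clip_negative clip negative output values to zero
#' @return square matrix of the reconstructed slice, in the phantom's
#'   attenuation units
#' @export
fbp_reconstruct <- function(sino, filter = c("ramp", "shepp-logan"),
                            clip_negative = FALSE) {
  stopifnot(inherits(sino, "sinogram"))
  filter <- match.arg(filter)
  n_ang <- nrow(sino$data)
  if (n_ang < 8) stop("at least 8 angles are required for FBP")
  n <- ncol(sino$data)
  pitch <- sino$detector_pitch_um
  m <- 2^ceiling(log2(2 * n))
  f <- fft_freq(m)
  H <- 2 * abs(f)
  if (filter == "shepp-logan") {
    sinc <- ifelse(f == 0, 1, sin(pi * f) / (pi * f))
    H <- H * sinc
  }
  ctr <- (n + 1) / 2
  s <- seq_len(n) - ctr
  xg <- matrix(s, n, n)          # rows: x coordinate
  yg <- matrix(s, n, n, byrow = TRUE)
  recon <- matrix(0, n, n)
  for (a in seq_len(n_ang)) {
    p <- sino$data[a, ] / pitch   # to per-pixel units
    pp <- c(p, rep(0, m - n))
    q <- Re(stats::fft(stats::fft(pp) * H, inverse = TRUE)) / m
    q <- q[seq_len(n)]
    th <- sino$angles_deg[a] * pi / 180
    t <- xg * cos(th) + yg * sin(th) + ctr
    t0 <- floor(t)
    ft <- t - t0
    v <- matrix(0, n, n)
    ok0 <- t0 >= 1 & t0 <= n
    ok1 <- t0 + 1 >= 1 & t0 + 1 <= n
    v[ok0] <- q[t0[ok0]] * (1 - ft[ok0])
    v[ok1] <- v[ok1] + q[t0[ok1] + 1] * ft[ok1]
    recon <- recon + v
  }
  recon <- recon * pi / (2 * n_ang) / pitch
  if (clip_negative) recon[recon < 0] <- 0
  recon
}

#' Artifact-consistency report for decoded versus raw slices
#'
#' Compares the background (outside-support) root-mean-square of a decoded
#' slice against the raw degraded slice; decoding should enhance common
#' features without generating background artifacts.
#'
#' @param decoded,raw reconstructed slices (matrices) on the same grid
#' @param phantom the attenuation map that was projected
#' @param support_threshold attenuation above this marks the support
#' @param margin_px support dilation margin in pixels
#' @param max_factor maximum tolerated ratio of decoded to raw background RMS
#' @return list with `background_rms_decoded`, `background_rms_raw`,
#'   `ratio`, `within_factor`
#' @export
artifact_consistency_check <- function(decoded, raw, phantom,
                                       support_threshold = 1e-6,
                                       margin_px = 3, max_factor = 1.0) {
  f <- image_data(phantom)
  if (!all(dim(decoded) == dim(f)) || !all(dim(raw) == dim(f)))
    stop("slices and phantom must share one grid")
  supp <- f > support_threshold
  if (margin_px > 0) {
    # dilate by a square structuring element via shifting
    d <- supp
    for (dr in -margin_px:margin_px) for (dc in -margin_px:margin_px) {
      rs <- seq_len(nrow(supp)) + dr
      cs <- seq_len(ncol(supp)) + dc
      okr <- rs >= 1 & rs <= nrow(supp)
      okc <- cs >= 1 & cs <= ncol(supp)
      d[okr, okc] <- d[okr, okc] | supp[rs[okr], cs[okc]]
    }
    supp <- d
  }
  bg <- !supp
  if (!any(bg)) stop("support covers the whole grid; no background remains")
  rms <- function(x) sqrt(mean(x[bg]^2))
  r_dec <- rms(decoded); r_raw <- rms(raw)
  ratio <- if (r_raw == 0) ifelse(r_dec == 0, 1, Inf) else r_dec / r_raw
  list(background_rms_decoded = r_dec,
       background_rms_raw = r_raw,
       ratio = ratio,
       within_factor = ratio <= max_factor + 1e-12)
}
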