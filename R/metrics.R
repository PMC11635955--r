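# Evaluation suite: frequency-resolved SNR against a ground-truth reference
# (normalized on an ultra-high-frequency noise band), region intensity
# ratios, contrast-to-noise ratios between named regions, centered 2D
# Fourier spectra, and line-section profiles.

#' Region-of-interest specification
#'
#' @param mask logical matrix marking the region
#' @param label short region name
#' @export
region_spec <- function(mask, label = "region") {
  mask <- as.matrix(mask)
  if (!is.logical(mask)) stop("mask must be logical")
  if (!any(mask)) stop("region mask '", label, "' is empty")
  structure(list(mask = mask, label = label), class = "region_spec")
}

#' Frequency-resolved SNR curve
#'
#' Radially averaged power spectra of the signal (the reference) and of the
#' noise (image minus the least-squares-scaled reference) are compared per
#' frequency bin: `SNR_dB(f) = 10 log10(P_signal / P_noise)`, offset so that
#' the mean over the normalization band (by default the top 10 percent of
#' represented frequencies, the ultra-high-frequency noise floor) is 0 dB.
#' Bins with fewer than 8 Fourier samples are merged outward; bins where the
#' noise power underflows are capped at +80 dB.
#'
#' @param image evaluated image (matrix or result object)
#' @param reference ground-truth reference of the same shape (long-exposure
#'   frame or noiseless truth)
#' @param pixel_pitch_um pixel spacing in micrometres (taken from the inputs
#'   when available)
#' @param n_bins number of radial frequency bins before merging
#' @param normalization_band `(f_lo, f_hi)` in inverse micrometres; `NULL`
#'   uses the top 10 percent of represented frequencies
#' @return an object of class `snr_curve` with `freq_bins` (bin centers,
#'   ascending, inverse micrometres), `snr_db`, `normalization_band`, the
#'   fitted `gain`, and the per-bin raw powers `p_signal` / `p_noise`
#'   (power-spectrum convention `|FFT|^2 / n_pixels`, so a white-noise field
#'   of variance `s^2` has per-bin noise power `s^2`)
#' @export
snr_curve <- function(image, reference, pixel_pitch_um = NULL, n_bins = 32,
                      normalization_band = NULL) {
  img <- image_data(image); ref <- image_data(reference)
  if (!all(dim(img) == dim(ref))) stop("image and reference shapes differ")
  if (sum(ref^2) == 0) stop("reference has zero power")
  if (is.null(pixel_pitch_um))
    pixel_pitch_um <- pitch_of(image, pitch_of(reference, 1))
  gain <- sum(img * ref) / sum(ref^2)
  noise <- img - gain * ref
  npix <- length(img)
  P_sig <- Mod(stats::fft(ref))^2 / npix
  P_noise <- Mod(stats::fft(noise))^2 / npix
  fr <- fft_freq(nrow(img)) / pixel_pitch_um
  fc <- fft_freq(ncol(img)) / pixel_pitch_um
  fmag <- sqrt(outer(fr^2, fc^2, "+"))
  fmax <- max(fmag)
  edges <- seq(0, fmax, length.out = n_bins + 1)
  bin <- pmin(findInterval(fmag, edges, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(bin, n_bins)
  # merge sparse bins outward (toward higher frequency)
  merged_id <- seq_len(n_bins)
  i <- 1
  while (i <= n_bins) {
    j <- i
    while (sum(counts[i:j]) < 8 && j < n_bins) j <- j + 1
    merged_id[i:j] <- i
    i <- j + 1
  }
  bin_m <- merged_id[bin]
  groups <- sort(unique(as.vector(bin_m)))
  sig_b <- vapply(groups, function(g) mean(P_sig[bin_m == g]), 0)
  noi_b <- vapply(groups, function(g) mean(P_noise[bin_m == g]), 0)
  ctr_b <- vapply(groups, function(g) mean(fmag[bin_m == g]), 0)
  ord <- order(ctr_b)
  sig_b <- sig_b[ord]; noi_b <- noi_b[ord]; ctr_b <- ctr_b[ord]
  if (is.null(normalization_band))
    normalization_band <- c(0.9 * fmax, fmax)
  underflow <- noi_b <= sig_b * 1e-15 | noi_b == 0
  snr_db <- ifelse(underflow, Inf, 10 * log10(sig_b / pmax(noi_b, 1e-300)))
  in_band <- ctr_b >= normalization_band[1] & ctr_b <= normalization_band[2]
  finite_band <- in_band & is.finite(snr_db)
  offset <- if (any(finite_band)) mean(snr_db[finite_band]) else 0
  snr_db <- snr_db - offset
  cap <- 80
  snr_db[!is.finite(snr_db) | snr_db > cap] <- cap
  structure(list(freq_bins = ctr_b, snr_db = snr_db,
                 normalization_band = normalization_band,
                 gain = gain, p_signal = sig_b, p_noise = noi_b),
            class = "snr_curve")
}

#' Mean SNR of a curve over a frequency band
#'
#' @param curve an [snr_curve()]
#' @param f_lo,f_hi band limits in inverse micrometres
#' @export
snr_band_mean <- function(curve, f_lo, f_hi) {
  stopifnot(inherits(curve, "snr_curve"))
  sel <- curve$freq_bins >= f_lo & curve$freq_bins <= f_hi
  if (!any(sel)) stop("no frequency bin falls inside [", f_lo, ", ", f_hi, "]")
  mean(curve$snr_db[sel])
}

#' Region-to-blank intensity ratio
#'
#' @param image matrix or result object
#' @param region a [region_spec()]
#' @param blank a [region_spec()] of the blank reference area, disjoint from
#'   `region`
#' @return `mean(image[region]) / mean(image[blank])`
#' @export
intensity_ratio <- function(image, region, blank) {
  stopifnot(inherits(region, "region_spec"), inherits(blank, "region_spec"))
  img <- image_data(image)
  if (!all(dim(region$mask) == dim(img)) || !all(dim(blank$mask) == dim(img)))
    stop("region masks must match the image shape")
  if (any(region$mask & blank$mask)) stop("region and blank masks overlap")
  mean(img[region$mask]) / mean(img[blank$mask])
}

#' Contrast-to-noise ratio between two regions
#'
#' Contrast-ratio convention: `CNR = (1 - r_A) / (1 - r_B)` where `r_X` is
#' the [intensity_ratio()] of region X against the blank area. For
#' absorption imaging `1 - r_X` is the absorption contrast of the region, so
#' values above 1 mean region A is the more strongly contrasted.
#'
#' @param image matrix or result object
#' @param region_a,region_b [region_spec()]s, pairwise disjoint with `blank`
#' @param blank blank-area [region_spec()]
#' @export
cnr <- function(image, region_a, region_b, blank) {
  if (any(region_a$mask & region_b$mask)) stop("regions A and B overlap")
  r_a <- intensity_ratio(image, region_a, blank)
  r_b <- intensity_ratio(image, region_b, blank)
  if (abs(1 - r_b) < 1e-15)
    stop("region B has zero absorption contrast; CNR undefined")
  (1 - r_a) / (1 - r_b)
}

#' Centered 2D Fourier magnitude spectrum
#'
#' @param image matrix or result object
#' @param log_scale return `log1p` of the magnitude
#' @return matrix of the same shape with the DC bin at the center pixel
#' @export
fourier_spectrum_2d <- function(image, log_scale = FALSE) {
  img <- image_data(image)
  if (length(img) == 0) stop("empty image")
  sp <- Mod(stats::fft(img))
  nr <- nrow(sp); nc <- ncol(sp)
  sh_r <- c((floor(nr / 2) + 1):nr, 1:floor(nr / 2))
  sh_c <- c((floor(nc / 2) + 1):nc, 1:floor(nc / 2))
  out <- sp[sh_r, sh_c, drop = FALSE]
  if (log_scale) log1p(out) else out
}

#' Line-section intensity profile
#'
#' Mean intensity across a band of given width, sampled along the line from
#' `start` to `end` (fractional (row, col) coordinates, 1-based) with
#' bilinear interpolation at unit-pixel steps.
#'
#' @param image matrix or result object
#' @param start,end (row, col) endpoints
#' @param width band width in pixels perpendicular to the line
#' @return numeric profile
#' @export
section_profile <- function(image, start, end, width = 1) {
  img <- image_data(image)
  dr <- end[1] - start[1]; dc <- end[2] - start[2]
  len <- sqrt(dr^2 + dc^2)
  if (len < 1e-9) stop("degenerate line: start and end coincide")
  n <- ceiling(len) + 1
  t <- seq(0, 1, length.out = n)
  ur <- dr / len; uc <- dc / len
  # perpendicular unit vector
  pr <- -uc; pc <- ur
  offs <- seq(-(width - 1) / 2, (width - 1) / 2, length.out = max(1, round(width)))
  prof <- matrix(0, n, length(offs))
  for (k in seq_along(offs)) {
    rr <- start[1] + t * dr + offs[k] * pr
    cc <- start[2] + t * dc + offs[k] * pc
    if (any(rr < 1 | rr > nrow(img) | cc < 1 | cc > ncol(img)))
      stop("line (with width) leaves the image")
    prof[, k] <- bilinear_interp(img, rr, cc)
  }
  rowMeans(prof)
}

#' Count prominent local minima of a profile
#'
#' A local minimum counts if its prominence (height of the lower of the two
#' enclosing maxima above the minimum) exceeds `min_prominence` times the
#' profile's range. Plateaus are collapsed before counting.
#'
#' @param profile numeric vector
#' @param min_prominence relative prominence threshold in `[0, 1)`
#' @return integer count
#' @export
count_profile_minima <- function(profile, min_prominence = 0.05) {
  # collapse exact plateaus
  keep <- c(TRUE, diff(profile) != 0)
  p <- profile[keep]
  n <- length(p)
  if (n < 3) return(0L)
  rng <- diff(range(p))
  if (rng == 0) return(0L)
  thr <- min_prominence * rng
  count <- 0L
  for (i in 2:(n - 1)) {
    if (p[i] < p[i - 1] && p[i] < p[i + 1]) {
      left_max <- max(p[1:(i - 1)])
      right_max <- max(p[(i + 1):n])
      # climb only until a deeper minimum would be reached on either side
      j <- i - 1; lm <- p[j]
      while (j >= 1 && p[j] >= p[i]) { lm <- max(lm, p[j]); j <- j - 1 }
      j <- i + 1; rm <- p[j]
      while (j <= n && p[j] >= p[i]) { rm <- max(rm, p[j]); j <- j + 1 }
      if (min(lm, rm) - p[i] >= thr) count <- count + 1L
    }
  }
  count
}

#' Export an SNR curve as CSV
#'
#' @param curve an [snr_curve()]
#' @param path output file
#' @export
write_snr_curve <- function(curve, path) {
  utils::write.csv(data.frame(freq_per_um = curve$freq_bins,
                              snr_db = curve$snr_db),
                   path, row.names = FALSE)
  invisible(path)
}
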