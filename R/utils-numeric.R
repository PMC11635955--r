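#' @keywords internal
"_PACKAGE"

# Shared low-level numerics: reflective padding, FFT convolution/correlation,
# bilinear interpolation, block binning, frequency grids, seed splitting.

#' DFT sample frequencies in cycles per sample
#'
#' @param n number of samples
#' @return numeric vector of length `n`, matching the usual FFT layout
#'   (nonnegative frequencies first, then negative).
#' @keywords internal
fft_freq <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

#' Reflective (symmetric) padding of a matrix
#'
#' Pads by mirroring with the edge sample included, the same convention as
#' `mode="symmetric"` boundary handling in common image-processing libraries.
#'
#' @param x numeric matrix
#' @param pr,pc padding (rows, cols) applied on each side
#' @keywords internal
pad_reflect <- function(x, pr, pc = pr) {
  nr <- nrow(x); nc <- ncol(x)
  if (pr > nr || pc > nc) {
    stop("reflective padding of (", pr, ", ", pc, ") exceeds image size (",
         nr, ", ", nc, "); kernel larger than image")
  }
  ri <- c(if (pr > 0) rev(seq_len(pr)) else integer(0),
          seq_len(nr),
          if (pr > 0) nr:(nr - pr + 1) else integer(0))
  ci <- c(if (pc > 0) rev(seq_len(pc)) else integer(0),
          seq_len(nc),
          if (pc > 0) nc:(nc - pc + 1) else integer(0))
  x[ri, ci, drop = FALSE]
}

# Embed a small kernel into an M x N array with its center wrapped to (1, 1),
# so that circular convolution realizes a linear shift by (i - center).
embed_kernel_wrapped <- function(kern, center, M, N) {
  kp <- matrix(0, M, N)
  nr <- nrow(kern); nc <- ncol(kern)
  ri <- ((seq_len(nr) - center[1]) %% M) + 1
  ci <- ((seq_len(nc) - center[2]) %% N) + 1
  kp[ri, ci] <- kp[ri, ci] + kern
  kp
}

default_center <- function(dm) (dm + 1L) %/% 2L + (dm %% 2L == 0L)

#' 2D convolution with reflective boundary handling
#'
#' Computes `out[x, y] = sum_{i,j} kern[i, j] * xR[x - (i - ci), y - (j - cj)]`
#' where `xR` is the symmetric extension of `x` and `(ci, cj)` the kernel
#' center. FFT-accelerated; exact up to round-off.
#'
#' @param x numeric matrix (image)
#' @param kern numeric matrix (kernel), not larger than `x` plus padding limits
#' @param center kernel center index (row, col); default middle pixel
#' @return matrix of the same shape as `x`
#' @export
conv2_reflect <- function(x, kern, center = NULL) {
  nr <- nrow(x); nc <- ncol(x)
  kr <- nrow(kern); kc <- ncol(kern)
  if (is.null(center)) center <- c(default_center(kr), default_center(kc))
  pr <- kr; pc <- kc
  xp <- pad_reflect(x, pr, pc)
  M <- nrow(xp); N <- ncol(xp)
  kp <- embed_kernel_wrapped(kern, center, M, N)
  out <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) / (M * N)
  out[(pr + 1):(pr + nr), (pc + 1):(pc + nc), drop = FALSE]
}

#' 2D cross-correlation with reflective boundary handling
#'
#' The adjoint of [conv2_reflect()] in its image argument: equivalent to
#' convolution with the kernel flipped in both axes.
#'
#' @inheritParams conv2_reflect
#' @export
corr2_reflect <- function(x, kern, center = NULL) {
  kr <- nrow(kern); kc <- ncol(kern)
  if (is.null(center)) center <- c(default_center(kr), default_center(kc))
  kflip <- kern[kr:1, kc:1, drop = FALSE]
  conv2_reflect(x, kflip, center = c(kr + 1 - center[1], kc + 1 - center[2]))
}

# Gradient of 0.5 * ||resid||^2 with respect to the kernel of
# conv2_reflect(scene, K, center): grad[i, j] = sum_xy resid[x, y] *
# sceneR[x - (i - ci), y - (j - cj)]. Computed by FFT cross-correlation on the
# padded scene.
conv2_reflect_kernel_grad <- function(scene, resid, kshape, center = NULL) {
  kr <- kshape[1]; kc <- kshape[2]
  if (is.null(center)) center <- c(default_center(kr), default_center(kc))
  pr <- kr; pc <- kc
  sp <- pad_reflect(scene, pr, pc)
  M <- nrow(sp); N <- ncol(sp)
  rp <- matrix(0, M, N)
  rp[(pr + 1):(pr + nrow(resid)), (pc + 1):(pc + ncol(resid))] <- resid
  # C[s] = sum_y rp[y] * sp[y + s]  via  ifft(Conj(fft(rp)) * fft(sp))
  C <- Re(stats::fft(Conj(stats::fft(rp)) * stats::fft(sp), inverse = TRUE)) / (M * N)
  idx_r <- ((center[1] - seq_len(kr)) %% M) + 1
  idx_c <- ((center[2] - seq_len(kc)) %% N) + 1
  C[idx_r, idx_c, drop = FALSE]
}

#' Bilinear interpolation on a matrix
#'
#' @param x numeric matrix
#' @param r,c fractional row/column coordinates (1-based), equal length
#' @param outside value used beyond the matrix extent
#' @return numeric vector of interpolated values
#' @keywords internal
bilinear_interp <- function(x, r, c, outside = 0) {
  nr <- nrow(x); nc <- ncol(x)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  val <- numeric(length(r))
  get <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- rep(outside, length(ri))
    v[ok] <- x[cbind(ri[ok], ci[ok])]
    v
  }
  v00 <- get(r0, c0);     v01 <- get(r0, c0 + 1)
  v10 <- get(r0 + 1, c0); v11 <- get(r0 + 1, c0 + 1)
  val <- v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
         v10 * fr * (1 - fc)       + v11 * fr * fc
  val
}

# Sum-pool a matrix over non-overlapping b x b blocks (detector binning);
# trailing rows/cols that do not fill a block are dropped.
bin_sum <- function(x, b) {
  if (b == 1) return(x)
  nr <- (nrow(x) %/% b) * b
  nc <- (ncol(x) %/% b) * b
  x <- x[seq_len(nr), seq_len(nc), drop = FALSE]
  xr <- rowsum(x, rep(seq_len(nr %/% b), each = b))
  t(rowsum(t(xr), rep(seq_len(nc %/% b), each = b)))
}

# Bilinear upsampling by an integer factor, mapping pixel centers so that the
# coarse grid is the block average of the fine grid (inverse of binning up to
# the bin^2 count scale).
upsample_bilinear <- function(x, factor) {
  if (factor == 1) return(x)
  nr <- nrow(x) * factor; nc <- ncol(x) * factor
  # fine-pixel centers in coarse-grid coordinates
  rr <- (seq_len(nr) - 0.5) / factor + 0.5
  cc <- (seq_len(nc) - 0.5) / factor + 0.5
  rr <- pmin(pmax(rr, 1), nrow(x))
  cc <- pmin(pmax(cc, 1), ncol(x))
  grid <- expand.grid(r = rr, c = cc)
  matrix(bilinear_interp(x, grid$r, grid$c), nr, nc)
}

# Deterministic child-seed derivation so pipeline stages can be rerun in
# isolation: Knuth multiplicative hash folded into the 32-bit signed range.
split_seed <- function(seed, stage) {
  s <- (as.double(seed) * 2654435761 + as.double(stage) * 40503) %% 2147483629
  as.integer(s)
}

# FNV-1a hash of a character representation, for provenance fingerprints.
fnv1a_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (as.double(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# Erode a logical mask by a square structuring element of half-width r.
mask_erode <- function(mask, r) {
  if (r <= 0) return(mask)
  out <- mask
  for (dr in -r:r) for (dc in -r:r) {
    sh <- matrix(FALSE, nrow(mask), ncol(mask))
    rs <- seq_len(nrow(mask)) + dr
    cs <- seq_len(ncol(mask)) + dc
    okr <- rs >= 1 & rs <= nrow(mask)
    okc <- cs >= 1 & cs <= ncol(mask)
    sh[okr, okc] <- mask[rs[okr], cs[okc]]
    out <- out & sh
  }
  out
}

image_data <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "source_image")) return(x$intensity)
  if (inherits(x, "captured_image")) return(x$counts)
  if (inherits(x, "reconstruction_result")) return(x$image)
  if (inherits(x, "psf_kernel")) return(x$grid)
  stop("cannot extract image data from object of class ",
       paste(class(x), collapse = "/"))
}

pitch_of <- function(x, default = NULL) {
  p <- NULL
  if (inherits(x, "source_image")) p <- x$pixel_pitch_um
  if (inherits(x, "psf_kernel")) p <- x$pixel_pitch_um
  if (inherits(x, "captured_image")) p <- x$pixel_pitch_um
  if (is.null(p)) p <- default
  p
}
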