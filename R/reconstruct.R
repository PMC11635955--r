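# Electronic decoder: Richardson-Lucy deconvolution with the (estimated)
# system kernel, plus the classical comparison filters.

#' Reconstruction result
#'
#' @param image nonnegative numeric matrix
#' @param iterations iterations actually run (0 for single-pass filters)
#' @param kernel_id provenance string, if a kernel was involved
#' @param method identifier of the producing method
#' @export
reconstruction_result <- function(image, iterations = 0L,
                                  kernel_id = NA_character_,
                                  method = "unknown") {
  if (any(image < 0)) stop("reconstructed image must be nonnegative")
  structure(list(image = image, iterations = as.integer(iterations),
                 kernel_id = kernel_id, method = method),
            class = "reconstruction_result")
}

#' Richardson-Lucy deconvolution
#'
#' Standard multiplicative updates
#' `x <- x * (K* corr (S / (K conv x)))` from a flat-field start, with
#' reflective boundary handling matching the forward model and an epsilon
#' floor guarding the ratio. Nonnegativity is preserved by construction. An
#' early stop triggers when the mean relative update falls below `stop_tol`.
#'
#' @param shot a [captured_image()], [reconstruction_result()] or matrix
#' @param kernel a normalized [psf_kernel()]
#' @param iterations maximum iterations, >= 1 (default 30)
#' @param stop_tol early-stop threshold on the mean relative update
#' @return a [reconstruction_result()]
#' @export
richardson_lucy <- function(shot, kernel, iterations = 30L,
                            stop_tol = 1e-4) {
  stopifnot(inherits(kernel, "psf_kernel"))
  if (iterations < 1) stop("iterations must be >= 1")
  S <- image_data(shot)
  if (all(S == 0)) stop("all-zero input cannot be deconvolved")
  if (any(S < 0)) stop("input must be nonnegative")
  K <- kernel$grid; ctr <- kernel$center
  eps <- 1e-12
  x <- matrix(mean(S), nrow(S), ncol(S))
  used <- iterations
  for (it in seq_len(iterations)) {
    denom <- conv2_reflect(x, K, ctr)
    ratio <- S / pmax(denom, eps)
    upd <- corr2_reflect(ratio, K, ctr)
    x_new <- x * upd
    rel <- mean(abs(x_new - x)) / max(mean(x), eps)
    x <- x_new
    if (rel < stop_tol) { used <- it; break }
  }
  x[x < 0] <- 0
  kid <- if (inherits(shot, "captured_image")) shot$kernel_id else NA_character_
  reconstruction_result(x, used, kid, "richardson_lucy")
}

# --- minimal orthogonal db4 wavelet machinery (8-tap Daubechies filters,
#     periodized transform) for the two wavelet baselines -------------------

db4_filters <- function() {
  h <- c(0.230377813308855230, 0.714846570552541500, 0.630880767929590400,
         -0.027983769416983850, -0.187034811718881140, 0.030841381835986965,
         0.032883011666982945, -0.010597401784997278)
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  list(h = h, g = g)
}

dwt_step_per <- function(x, f) {
  n <- length(x); m <- length(f$h)
  idx <- outer(seq(0, n - 2, by = 2), seq_len(m) - 1, "+") %% n + 1
  xm <- matrix(x[idx], ncol = m)
  list(a = as.vector(xm %*% f$h), d = as.vector(xm %*% f$g))
}

idwt_step_per <- function(a, d, f) {
  n2 <- length(a) * 2; m <- length(f$h)
  x <- numeric(n2)
  pos <- outer(seq(0, n2 - 2, by = 2), seq_len(m) - 1, "+") %% n2 + 1
  for (k in seq_len(m)) {
    x[pos[, k]] <- x[pos[, k]] + a * f$h[k] + d * f$g[k]
  }
  x
}

dwt2_per <- function(x, levels, f) {
  out <- list()
  cur <- x
  for (l in seq_len(levels)) {
    n <- nrow(cur); m <- ncol(cur)
    rows_a <- matrix(0, n, m / 2); rows_d <- rows_a
    for (i in seq_len(n)) {
      s <- dwt_step_per(cur[i, ], f); rows_a[i, ] <- s$a; rows_d[i, ] <- s$d
    }
    LL <- matrix(0, n / 2, m / 2); LH <- LL; HL <- LL; HH <- LL
    for (j in seq_len(m / 2)) {
      s <- dwt_step_per(rows_a[, j], f); LL[, j] <- s$a; HL[, j] <- s$d
      s <- dwt_step_per(rows_d[, j], f); LH[, j] <- s$a; HH[, j] <- s$d
    }
    out[[l]] <- list(LH = LH, HL = HL, HH = HH)
    cur <- LL
  }
  list(approx = cur, detail = out)
}

idwt2_per <- function(w, f) {
  cur <- w$approx
  for (l in rev(seq_along(w$detail))) {
    d <- w$detail[[l]]
    n2 <- nrow(cur) * 2; m <- ncol(cur)
    rows_a <- matrix(0, n2, m); rows_d <- rows_a
    for (j in seq_len(m)) {
      rows_a[, j] <- idwt_step_per(cur[, j], d$HL[, j], f)
      rows_d[, j] <- idwt_step_per(d$LH[, j], d$HH[, j], f)
    }
    out <- matrix(0, n2, m * 2)
    for (i in seq_len(n2)) {
      out[i, ] <- idwt_step_per(rows_a[i, ], rows_d[i, ], f)
    }
    cur <- out
  }
  cur
}

wavelet_denoise <- function(img, mode = c("soft", "hard"), levels = 3) {
  mode <- match.arg(mode)
  f <- db4_filters()
  # pad reflectively to a multiple of 2^levels
  mult <- 2^levels
  pr <- (mult - nrow(img) %% mult) %% mult
  pc <- (mult - ncol(img) %% mult) %% mult
  padded <- img
  if (pr > 0) padded <- rbind(padded, padded[nrow(padded):(nrow(padded) - pr + 1), , drop = FALSE])
  if (pc > 0) padded <- cbind(padded, padded[, ncol(padded):(ncol(padded) - pc + 1), drop = FALSE])
  w <- dwt2_per(padded, levels, f)
  hh1 <- w$detail[[1]]$HH
  sigma <- stats::median(abs(hh1)) / 0.6745
  thr <- sigma * sqrt(2 * log(length(padded)))
  shrink <- function(x) {
    if (mode == "soft") sign(x) * pmax(abs(x) - thr, 0)
    else x * (abs(x) > thr)
  }
  w$detail <- lapply(w$detail, function(d) lapply(d, shrink))
  rec <- idwt2_per(w, f)
  rec[seq_len(nrow(img)), seq_len(ncol(img)), drop = FALSE]
}

gaussian_kernel_2d <- function(sd) {
  if (sd <= 0) return(matrix(1, 1, 1))
  rad <- max(1L, ceiling(4 * sd))
  g1 <- exp(-((-rad):rad)^2 / (2 * sd^2))
  k <- outer(g1, g1)
  k / sum(k)
}

median_filter <- function(img, w) {
  rad <- (w - 1) %/% 2
  p <- pad_reflect(img, rad, rad)
  nr <- nrow(img); nc <- ncol(img)
  stack <- matrix(0, nr * nc, w * w)
  k <- 1
  for (dr in 0:(w - 1)) for (dc in 0:(w - 1)) {
    stack[, k] <- as.vector(p[(1 + dr):(nr + dr), (1 + dc):(nc + dc)])
    k <- k + 1
  }
  matrix(apply(stack, 1, stats::median), nr, nc)
}

#' Classical baseline filters
#'
#' Applies one of the named classical denoising/sharpening filters used for
#' comparison against the learned decoder. All are deterministic.
#'
#' Methods and their parameters (with defaults):
#' `gaussian` (`sd = 1.5` px), `mean` (`window = 3`), `median`
#' (`window = 3`), `lowpass` (`cutoff = 0.25` cycles/px, separable frequency
#' mask so any cutoff at or above Nyquist is the identity), `wavelet_soft` /
#' `wavelet_hard` (db4, `levels = 3`, universal threshold from the
#' finest-scale diagonal band), `laplacian_sharpen` (`strength = 1`).
#'
#' @param shot a [captured_image()], [reconstruction_result()] or matrix
#' @param method one of the method names above
#' @param params named list of method parameters overriding the defaults
#' @return a [reconstruction_result()]
#' @export
baseline_filter <- function(shot, method, params = list()) {
  valid <- c("gaussian", "mean", "median", "lowpass",
             "wavelet_soft", "wavelet_hard", "laplacian_sharpen")
  if (!is.character(method) || length(method) != 1 || !(method %in% valid))
    stop("unknown method '", method, "'; valid methods: ",
         paste(valid, collapse = ", "))
  img <- image_data(shot)
  out <- switch(method,
    gaussian = {
      sd <- if (is.null(params$sd)) 1.5 else params$sd
      conv2_reflect(img, gaussian_kernel_2d(sd))
    },
    mean = {
      w <- if (is.null(params$window)) 3L else params$window
      conv2_reflect(img, matrix(1 / w^2, w, w))
    },
    median = {
      w <- if (is.null(params$window)) 3L else params$window
      median_filter(img, w)
    },
    lowpass = {
      cutoff <- if (is.null(params$cutoff)) 0.25 else params$cutoff
      fr <- fft_freq(nrow(img)); fc <- fft_freq(ncol(img))
      mask <- outer(abs(fr) <= cutoff, abs(fc) <= cutoff)
      Re(stats::fft(stats::fft(img) * mask, inverse = TRUE)) / length(img)
    },
    wavelet_soft = wavelet_denoise(img, "soft",
                                   if (is.null(params$levels)) 3 else params$levels),
    wavelet_hard = wavelet_denoise(img, "hard",
                                   if (is.null(params$levels)) 3 else params$levels),
    laplacian_sharpen = {
      strength <- if (is.null(params$strength)) 1 else params$strength
      lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
      img - strength * conv2_reflect(img, lap)
    })
  out[out < 0] <- 0
  reconstruction_result(out, 0L, NA_character_, method)
}

#' End-to-end decoding pipeline
#'
#' Upsamples a binned detector frame back to source resolution (bilinear,
#' count-preserving) and applies Richardson-Lucy deconvolution with the
#' estimated kernel.
#'
#' @param shot a [captured_image()]
#' @param estimated an [estimated_kernel()] from [estimate_kernel()] (a bare
#'   [psf_kernel()] is also accepted)
#' @param iterations Richardson-Lucy iterations
#' @param stop_tol early-stop threshold passed to [richardson_lucy()]
#' @return a [reconstruction_result()] at source resolution
#' @export
reconstruct_pipeline <- function(shot, estimated, iterations = 30L,
                                 stop_tol = 1e-4) {
  stopifnot(inherits(shot, "captured_image"))
  kern <- if (inherits(estimated, "estimated_kernel")) estimated$kernel
          else estimated
  stopifnot(inherits(kern, "psf_kernel"))
  b <- shot$settings$bin_factor
  S <- shot$counts
  if (b > 1) S <- upsample_bilinear(S, b) / b^2
  res <- richardson_lucy(S, kern, iterations, stop_tol)
  res$kernel_id <- if (inherits(estimated, "estimated_kernel"))
    fnv1a_hash(signif(kern$grid, 8)) else res$kernel_id
  res$method <- "reconstruct_pipeline"
  res
}
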