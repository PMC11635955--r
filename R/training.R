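# Decoder training: estimate the effective system kernel from one capture of
# a known calibration sample by minimizing the least-squares inference target
# ||S - I_known (x) K||_F^2 over K, with a nonnegativity projection and
# renormalization every epoch. The per-epoch Frobenius loss and a kernel
# stability trace are recorded.

#' Calibration pair
#'
#' @param known_scene the ground-truth [source_image()] of the calibration
#'   sample
#' @param observed the [captured_image()] of that sample
#' @return an object of class `calibration_pair`
#' @export
calibration_pair <- function(known_scene, observed) {
  stopifnot(inherits(known_scene, "source_image"),
            inherits(observed, "captured_image"))
  b <- observed$settings$bin_factor
  if (!all(dim(observed$counts) * b == dim(known_scene$intensity)))
    stop("observed shape times bin_factor must match the known scene")
  structure(list(known_scene = known_scene, observed = observed),
            class = "calibration_pair")
}

#' Frobenius training loss
#'
#' Euclidean (Frobenius) norm of the error matrix between an observed frame
#' and a predicted frame.
#'
#' @param observed matrix or [captured_image()]
#' @param predicted matrix of the same shape
#' @return nonnegative scalar
#' @export
frobenius_loss <- function(observed, predicted) {
  a <- image_data(observed); b <- image_data(predicted)
  if (!all(dim(a) == dim(b))) stop("shape mismatch between observed (",
                                   paste(dim(a), collapse = "x"),
                                   ") and predicted (",
                                   paste(dim(b), collapse = "x"), ")")
  sqrt(sum((a - b)^2))
}

#' Per-epoch training trace
#'
#' @param loss per-epoch Frobenius losses
#' @param stability per-epoch stability values (see [stability()])
#' @export
training_trace <- function(loss, stability) {
  if (length(loss) != length(stability))
    stop("loss and stability traces must have equal length")
  if (any(loss < 0)) stop("losses must be nonnegative")
  structure(list(loss = loss, stability = stability,
                 epochs = length(loss)),
            class = "training_trace")
}

#' Kernel stability trace
#'
#' Stability of epoch e is `1 - ||K_e - K_{e-1}||_F / ||K_{e-1}||_F` (kernels
#' are nonnegative so absolute values are the kernels themselves); a value of
#' 1 means the kernel did not move. The first epoch is measured against the
#' initial kernel.
#'
#' @param trace a [training_trace()] with at least two epochs
#' @return numeric vector of per-epoch stabilities on `(-Inf, 1]`
#' @export
stability <- function(trace) {
  stopifnot(inherits(trace, "training_trace"))
  if (trace$epochs < 2)
    stop("stability requires a trace with at least 2 epochs")
  trace$stability
}

#' Estimate the effective system kernel from one calibration exposure
#'
#' Projected-gradient descent on the least-squares objective
#' `||S - I_known (x) K||_F^2` with a nonnegativity projection and unit-sum
#' renormalization each epoch. The gradient is projected onto the zero-sum
#' subspace (the component the renormalization would cancel), the step length
#' follows alternating Barzilai-Borwein estimates and is backtracked until
#' descent holds, so the recorded loss is non-increasing. If the detector
#' frame is binned it is bilinearly upsampled to scene resolution first; both
#' sides are normalized by their means so the fit is invariant to the
#' calibration scene's global intensity scale.
#'
#' @param calib a [calibration_pair()]
#' @param kernel_shape (rows, cols) of the estimated kernel, both odd
#' @param epochs number of training epochs (default 60)
#' @param step initial gradient step length; `NULL` uses the inverse of the
#'   scene power spectrum's largest non-DC mode (a Lipschitz bound on the
#'   zero-sum subspace)
#' @param seed integer seed (the optimizer itself is deterministic; the seed
#'   is recorded for provenance)
#' @param patience epochs without loss improvement before a warning status is
#'   set on the result
#' @return an object of class `estimated_kernel` with elements `kernel`
#'   ([psf_kernel()]), `trace` ([training_trace()]), `final_loss`, and
#'   `status` (`"converged"` or `"stalled"`)
#' @export
estimate_kernel <- function(calib, kernel_shape = c(33, 33), epochs = 60L,
                            step = NULL, seed = 1L, patience = 10L) {
  stopifnot(inherits(calib, "calibration_pair"))
  if (any(kernel_shape %% 2 == 0))
    stop("kernel_shape must be odd in both dimensions")
  scene <- calib$known_scene$intensity
  obs <- calib$observed$counts
  b <- calib$observed$settings$bin_factor
  if (b > 1) {
    obs <- upsample_bilinear(obs, b) / b^2
  }
  # normalize both sides by their means: removes the photon budget, the
  # kernel's collection gain and any global intensity scale from the fit
  if (mean(obs) <= 0) stop("observed calibration frame is all zero")
  scene_n <- scene / mean(scene)
  obs_n <- obs / mean(obs)
  kr <- kernel_shape[1]; kc <- kernel_shape[2]
  ctr <- c(default_center(kr), default_center(kc))
  K <- matrix(0, kr, kc); K[ctr[1], ctr[2]] <- 1
  # Lipschitz bound of the gradient restricted to the zero-sum subspace:
  # the largest non-DC mode of the padded scene's power spectrum (the DC
  # component of the step is cancelled by the renormalization)
  if (is.null(step)) {
    pw <- Mod(stats::fft(pad_reflect(scene_n, kr, kc)))^2
    step <- 1 / max(pw[-1])
  }
  loss_tr <- numeric(epochs)
  stab_tr <- numeric(epochs)
  resid <- obs_n - conv2_reflect(scene_n, K, ctr)
  cur_loss <- sqrt(sum(resid^2))
  stalled_for <- 0L
  grad_prev <- NULL; K_prev <- NULL
  for (e in seq_len(epochs)) {
    grad <- -conv2_reflect_kernel_grad(scene_n, resid, c(kr, kc), ctr)
    grad <- grad - mean(grad)
    if (!is.null(grad_prev)) {
      sk <- K - K_prev; yk <- grad - grad_prev
      bb1_den <- sum(sk * yk); bb2_num <- sum(yk * yk)
      s1 <- if (bb1_den > 0) sum(sk * sk) / bb1_den else step
      s2 <- if (bb2_num > 0 && bb1_den > 0) bb1_den / bb2_num else step
      cand <- if (e %% 2 == 0) s1 else s2
      if (is.finite(cand) && cand > 0) step <- cand
    }
    improved <- FALSE
    st <- step
    for (bt in 1:40) {
      K_new <- K - st * grad
      K_new[K_new < 0] <- 0
      s <- sum(K_new)
      if (s > 0) K_new <- K_new / s else { K_new <- K; break }
      resid_new <- obs_n - conv2_reflect(scene_n, K_new, ctr)
      new_loss <- sqrt(sum(resid_new^2))
      if (new_loss <= cur_loss) { improved <- TRUE; break }
      st <- st / 2
    }
    K_prev <- K; grad_prev <- grad
    if (improved) {
      dk <- sqrt(sum((K_new - K)^2)) / max(sqrt(sum(K^2)), 1e-300)
      K <- K_new; resid <- resid_new
      if (new_loss < cur_loss * (1 - 1e-12)) stalled_for <- 0L
      else stalled_for <- stalled_for + 1L
      cur_loss <- new_loss
    } else {
      dk <- 0
      stalled_for <- stalled_for + 1L
    }
    loss_tr[e] <- cur_loss
    stab_tr[e] <- 1 - dk
  }
  status <- if (stalled_for >= patience) "stalled" else "converged"
  if (status == "stalled")
    warning("training loss failed to decrease over the last ", stalled_for,
            " epochs")
  structure(list(kernel = psf_kernel(K, calib$known_scene$pixel_pitch_um,
                                     center = ctr),
                 trace = training_trace(loss_tr, stab_tr),
                 final_loss = cur_loss,
                 status = status,
                 seed = as.integer(seed)),
            class = "estimated_kernel")
}

#' Export a training trace as CSV
#'
#' @param trace a [training_trace()]
#' @param path output file
#' @export
write_training_trace <- function(trace, path) {
  utils::write.csv(data.frame(epoch = seq_len(trace$epochs),
                              loss = trace$loss,
                              stability = trace$stability),
                   path, row.names = FALSE)
  invisible(path)
}
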