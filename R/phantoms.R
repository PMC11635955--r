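# Synthetic scenes emulating the experimental samples: an etched digit glyph,
# a fixed-pitch absorption fringe card, fiber textures, and a two-region
# absorber (smooth tube analog next to a textured fin analog). Intensities
# are transmitted-flux fractions: 1.0 is the blank field, darker is denser.

#' Source image (ground-truth scene)
#'
#' @param intensity numeric matrix with entries in `[0, 1]` (relative
#'   transmitted flux; 1 is the blank field)
#' @param pixel_pitch_um pixel spacing in micrometres
#' @param regions optional named list of logical region masks
#' @return an object of class `source_image`
#' @export
source_image <- function(intensity, pixel_pitch_um = 1, regions = NULL) {
  intensity <- as.matrix(intensity)
  if (any(intensity < 0 | intensity > 1))
    stop("intensity entries must lie in [0, 1]")
  structure(list(intensity = intensity, pixel_pitch_um = pixel_pitch_um,
                 regions = regions),
            class = "source_image")
}

#' Periodic fringe phantom
#'
#' Blank field with `n_lines` equally spaced absorbing lines (dark bands of
#' width half the pitch), mimicking a fixed-pitch resolution fringe card.
#' Lines run vertically, so a horizontal section crosses all of them.
#'
#' @param size (rows, cols) in pixels
#' @param pitch_um line spacing in micrometres (>= 2 pixels)
#' @param n_lines number of absorbing lines
#' @param depth absorbed fraction in `[0, 1]`; transmitted intensity within a
#'   line is `1 - depth`
#' @param pixel_pitch_um pixel spacing in micrometres
#' @return a [source_image()] with regions `stripe` (the fringe field,
#'   including gaps) and `blank`
#' @export
make_fringe_phantom <- function(size = c(256, 256), pitch_um = 3,
                                n_lines = 7, depth = 0.5,
                                pixel_pitch_um = 0.5) {
  if (pitch_um < 2 * pixel_pitch_um)
    stop("pitch_um must be at least 2 pixels")
  nr <- size[1]; nc <- size[2]
  img <- matrix(1, nr, nc)
  stripe_mask <- matrix(FALSE, nr, nc)
  if (n_lines > 0 && depth > 0) {
    pitch_px <- max(2L, round(pitch_um / pixel_pitch_um))
    width_px <- max(1L, round(pitch_px / 2))
    extent <- n_lines * pitch_px   # n whole periods, line first then gap
    if (extent > nc) stop("lines exceed image width: need at least ",
                          extent, " columns")
    s0 <- floor((nc - extent) / 2) + 1L
    for (k in seq_len(n_lines)) {
      start <- s0 + (k - 1L) * pitch_px
      img[, start:(start + width_px - 1L)] <- 1 - depth
    }
    stripe_mask[, s0:(s0 + extent - 1L)] <- TRUE
  }
  source_image(img, pixel_pitch_um,
               regions = list(stripe = stripe_mask, blank = !stripe_mask))
}

# 5 x 7 bitmap digit font (rows top to bottom, "1" marks an absorbing stroke).
glyph_font <- function() {
  rows <- list(
    "0" = c("01110","10001","10011","10101","11001","10001","01110"),
    "1" = c("00100","01100","00100","00100","00100","00100","01110"),
    "2" = c("01110","10001","00001","00010","00100","01000","11111"),
    "3" = c("11111","00010","00100","00010","00001","10001","01110"),
    "4" = c("00010","00110","01010","10010","11111","00010","00010"),
    "5" = c("11111","10000","11110","00001","00001","10001","01110"),
    "6" = c("00110","01000","10000","11110","10001","10001","01110"),
    "7" = c("11111","00001","00010","00100","01000","01000","01000"),
    "8" = c("01110","10001","10001","01110","10001","10001","01110"),
    "9" = c("01110","10001","10001","01111","00001","00010","01100"))
  lapply(rows, function(r) {
    do.call(rbind, lapply(r, function(s) as.integer(strsplit(s, "")[[1]]) ))
  })
}

#' Etched-digit glyph phantom
#'
#' Rasterizes a digit string as absorbing strokes on a blank field, emulating
#' a number etched in a thin film. Glyphs come from a built-in 5 x 7 bitmap
#' font scaled by the largest integer factor that fits the image with a 10
#' percent margin.
#'
#' @param size (rows, cols) in pixels
#' @param text nonempty string of digits 0-9
#' @param depth absorbed fraction of the strokes
#' @param pixel_pitch_um pixel spacing in micrometres
#' @return a [source_image()] with regions `glyph` and `blank`
#' @export
make_glyph_phantom <- function(size = c(256, 256), text = "239",
                               depth = 0.7, pixel_pitch_um = 1) {
  if (!nzchar(text)) stop("text must be nonempty")
  chars <- strsplit(text, "")[[1]]
  font <- glyph_font()
  if (!all(chars %in% names(font)))
    stop("unrenderable glyph(s): ",
         paste(setdiff(chars, names(font)), collapse = ", "),
         " (only digits 0-9 are available)")
  nchars <- length(chars)
  # glyph block: chars of 5 cols + 1 col gap between them, 7 rows
  block_w <- nchars * 5 + (nchars - 1)
  block_h <- 7
  nr <- size[1]; nc <- size[2]
  scale <- max(1L, floor(min(0.8 * nc / block_w, 0.8 * nr / block_h)))
  img <- matrix(1, nr, nc)
  r0 <- floor((nr - block_h * scale) / 2)
  c0 <- floor((nc - block_w * scale) / 2)
  mask <- matrix(FALSE, nr, nc)
  for (k in seq_len(nchars)) {
    bm <- font[[chars[k]]]
    offc <- c0 + (k - 1) * 6 * scale
    for (i in 1:7) for (j in 1:5) {
      if (bm[i, j] == 1) {
        rr <- r0 + ((i - 1) * scale + 1):(i * scale)
        cc <- offc + ((j - 1) * scale + 1):(j * scale)
        mask[rr, cc] <- TRUE
      }
    }
  }
  img[mask] <- 1 - depth
  source_image(img, pixel_pitch_um, regions = list(glyph = mask, blank = !mask))
}

#' Two-region absorption phantom
#'
#' A smooth circular region A (the tube analog) at transmitted fraction
#' `ratio_a` and a textured region B (the fin analog) whose mean transmitted
#' fraction is exactly `ratio_b`, on a blank field. Region B's texture is a
#' seeded bundle of fine oblique stripes with random phase jitter; it is
#' recentered so the region mean is unaffected by the texture.
#'
#' @param size (rows, cols) in pixels
#' @param ratio_a transmitted fraction of region A in `[0, 1]`
#' @param ratio_b mean transmitted fraction of region B in `[0, 1]`
#' @param texture_in_b add fine-scale texture to region B
#' @param texture_amplitude peak-to-mean amplitude of the texture modulation
#' @param texture_period_um stripe period of the texture in micrometres; the
#'   default of 10 keeps the fin rays resolvable on a detector binned 2x at
#'   1 um source pitch (5 detector pixels per period)
#' @param texture_angle_deg orientation of the fin rays: the angle of the
#'   stripe normal from the row axis. Fin rays have a definite anatomical
#'   direction, and imaging with a 1D grating aligns the sample's texture
#'   with the grating axis, so the default keeps the stripe variation close
#'   to the axis a line-grating kernel preserves.
#' @param seed integer seed for the texture jitter
#' @param pixel_pitch_um pixel spacing in micrometres
#' @return a [source_image()] with regions `a`, `b` and `blank`
#' @export
make_two_region_phantom <- function(size = c(256, 256), ratio_a = 0.858,
                                    ratio_b = 0.881, texture_in_b = TRUE,
                                    texture_amplitude = 0.08,
                                    texture_period_um = 10,
                                    texture_angle_deg = 15,
                                    seed = 1, pixel_pitch_um = 1) {
  if (ratio_a < 0 || ratio_a > 1 || ratio_b < 0 || ratio_b > 1)
    stop("ratios must lie in [0, 1]")
  nr <- size[1]; nc <- size[2]
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  rad <- min(nr, nc) * 0.21
  mask_a <- (rr - nr / 2)^2 + (cc - nc * 0.28)^2 <= rad^2
  mask_b <- (rr - nr / 2)^2 + (cc - nc * 0.72)^2 <= rad^2
  img <- matrix(1, nr, nc)
  img[mask_a] <- ratio_a
  img[mask_b] <- ratio_b
  if (texture_in_b) {
    withr_seed <- function(expr) { set.seed(seed, kind = "Mersenne-Twister"); expr }
    tex <- withr_seed({
      phi <- stats::runif(1, 0, 2 * pi)
      ang <- texture_angle_deg * pi / 180
      jitter <- matrix(stats::rnorm(nr * nc, sd = 0.35), nr, nc)
      period_px <- texture_period_um / pixel_pitch_um
      sin(2 * pi * (rr * cos(ang) + cc * sin(ang)) / period_px + phi + jitter)
    })
    tvals <- tex[mask_b]
    tvals <- tvals - mean(tvals)
    vals <- ratio_b + texture_amplitude * tvals
    img[mask_b] <- pmin(pmax(vals, 0), 1)
    # re-center after clamping so the region mean is exactly ratio_b
    img[mask_b] <- img[mask_b] - (mean(img[mask_b]) - ratio_b)
    img[mask_b] <- pmin(pmax(img[mask_b], 0), 1)
  }
  # feature-measurement masks mimicking regions drawn around the visible
  # structures: the tube interior away from its edge, and the dark texture
  # stripes inside the fin region (where enhancement or washout of the fine
  # features moves the measured mean)
  margin <- max(3L, round(min(nr, nc) / 24))
  a_int <- mask_erode(mask_a, margin)
  b_int <- mask_erode(mask_b, margin)
  b_dark <- b_int & img < ratio_b - 1e-12
  if (!any(b_dark)) b_dark <- b_int
  source_image(img, pixel_pitch_um,
               regions = list(a = mask_a, b = mask_b,
                              a_interior = a_int, b_dark = b_dark,
                              blank = !(mask_a | mask_b)))
}

#' Random fiber-texture phantom
#'
#' Seeded random smooth curves of a given width and absorption on a blank
#' field, emulating plant-fiber tissue. Fibers are drawn sequentially with
#' per-fiber child seeds, so increasing `n_fibers` extends (never changes)
#' the existing set.
#'
#' @param size (rows, cols) in pixels
#' @param n_fibers number of fibers (0 gives a uniform field)
#' @param width_um fiber width in micrometres
#' @param depth absorbed fraction within a fiber
#' @param seed integer seed
#' @param pixel_pitch_um pixel spacing in micrometres
#' @return a [source_image()] with regions `fiber` and `blank`
#' @export
make_fiber_phantom <- function(size = c(256, 256), n_fibers = 12,
                               width_um = 3, depth = 0.5, seed = 1,
                               pixel_pitch_um = 1) {
  nr <- size[1]; nc <- size[2]
  mask <- matrix(FALSE, nr, nc)
  half_w <- width_um / pixel_pitch_um / 2
  rad <- max(1L, ceiling(half_w))
  disk <- {
    dd <- expand.grid(dr = -rad:rad, dc = -rad:rad)
    dd[dd$dr^2 + dd$dc^2 <= half_w^2 + 0.25, , drop = FALSE]
  }
  if (n_fibers > 0) {
    for (f in seq_len(n_fibers)) {
      set.seed(split_seed(seed, f), kind = "Mersenne-Twister")
      r <- stats::runif(1, nr * 0.1, nr * 0.9)
      c <- stats::runif(1, nc * 0.1, nc * 0.9)
      ang <- stats::runif(1, 0, 2 * pi)
      nsteps <- round(0.7 * min(nr, nc))
      for (s in seq_len(nsteps)) {
        ang <- ang + stats::rnorm(1, sd = 0.08)
        r <- r + sin(ang); c <- c + cos(ang)
        ri <- round(r) + disk$dr; ci <- round(c) + disk$dc
        ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
        if (any(ok)) mask[cbind(ri[ok], ci[ok])] <- TRUE
      }
    }
  }
  img <- matrix(1, nr, nc)
  img[mask] <- 1 - depth
  source_image(img, pixel_pitch_um, regions = list(fiber = mask, blank = !mask))
}
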