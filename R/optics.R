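# Optical encoder design: escape-cone geometry of a high-index scintillator,
# the scalar grating equation of a periodic metasurface on its exit face, and
# aggregation of admitted diffraction orders into an incoherent point-spread
# function (the optical convolution kernel).

#' Optical system specification
#'
#' Describes the scintillator/detector train around the metasurface: the
#' scintillator refractive index, the acceptance half-angle of the collection
#' optics, the effective ray-mapping propagation distance from the exit face
#' to the detector, and an optional residual system kernel (all optics other
#' than the metasurface).
#'
#' @param n_scint refractive index of the scintillator (Ce:YAG default 1.82)
#' @param acceptance_half_angle_deg acceptance half-angle of the collection
#'   optics, degrees in (0, 90]. The default of 10 degrees is chosen so that a
#'   200 nm-period structure passes no diffracted visible light while a
#'   300 nm period passes its first order (see the package vignette).
#' @param propagation_distance_um effective exit-face-to-detector ray-mapping
#'   distance in micrometres
#' @param system_kernel optional [psf_kernel()] for the residual optics;
#'   `NULL` means a single-pixel delta
#' @return an object of class `optical_system`
#' @export
optical_system <- function(n_scint = 1.82,
                           acceptance_half_angle_deg = 10,
                           propagation_distance_um = 50,
                           system_kernel = NULL) {
  if (!is.numeric(n_scint) || n_scint < 1)
    stop("n_scint must be a refractive index >= 1")
  if (acceptance_half_angle_deg <= 0 || acceptance_half_angle_deg > 90)
    stop("acceptance_half_angle_deg must lie in (0, 90]")
  if (propagation_distance_um <= 0)
    stop("propagation_distance_um must be positive")
  if (!is.null(system_kernel)) {
    stopifnot(inherits(system_kernel, "psf_kernel"))
    if (any(system_kernel$grid < 0))
      stop("system_kernel must be nonnegative")
  }
  structure(list(n_scint = n_scint,
                 acceptance_half_angle_deg = acceptance_half_angle_deg,
                 propagation_distance_um = propagation_distance_um,
                 system_kernel = system_kernel),
            class = "optical_system")
}

#' Metasurface specification
#'
#' @param period_nm structure period in nanometres (ignored for
#'   `geometry = "none"`)
#' @param geometry `"grating_1d"` for a one-dimensional line grating,
#'   `"isotropic_2d"` for an isotropic periodic structure, or `"none"` for the
#'   plain scintillator-air interface (the unmodified-system baseline)
#' @param efficiency_model `"uniform_orders"` (equal weight to every admitted
#'   order) or `"user_table"` with `efficiency_table`
#' @param order_range maximum |m| diffraction order considered
#' @param efficiency_table named numeric vector of per-order efficiencies,
#'   names are order indices (e.g. `c("-1" = 0.3, "0" = 0.4, "1" = 0.3)`);
#'   required for `efficiency_model = "user_table"`
#' @return an object of class `metasurface`
#' @export
metasurface <- function(period_nm = NA_real_,
                        geometry = c("grating_1d", "isotropic_2d", "none"),
                        efficiency_model = c("uniform_orders", "user_table"),
                        order_range = 2L,
                        efficiency_table = NULL) {
  geometry <- match.arg(geometry)
  efficiency_model <- match.arg(efficiency_model)
  if (geometry != "none" && (!is.numeric(period_nm) || is.na(period_nm) || period_nm <= 0))
    stop("period_nm must be positive for geometry '", geometry, "'")
  if (order_range < 0) stop("order_range must be >= 0")
  if (efficiency_model == "user_table" && is.null(efficiency_table))
    stop("efficiency_table is required for efficiency_model = 'user_table'")
  if (geometry == "none") order_range <- 0L
  structure(list(period_nm = period_nm, geometry = geometry,
                 efficiency_model = efficiency_model,
                 order_range = as.integer(order_range),
                 efficiency_table = efficiency_table),
            class = "metasurface")
}

#' Scintillator emission spectrum
#'
#' Discrete polychromatic emission spectrum of the scintillator fluorescence.
#' Weights are normalized to sum to one. The default is uniform over the
#' visible band 400-700 nm at 10 nm steps.
#'
#' @param wavelength_nm wavelengths in nanometres, all positive
#' @param weight nonnegative relative weights (recycled uniform by default)
#' @return an object of class `emission_spectrum`
#' @export
emission_spectrum <- function(wavelength_nm = seq(400, 700, by = 10),
                              weight = NULL) {
  if (length(wavelength_nm) == 0) stop("spectrum must contain at least one wavelength")
  if (any(wavelength_nm <= 0)) stop("wavelengths must be positive")
  if (is.null(weight)) weight <- rep(1, length(wavelength_nm))
  if (length(weight) != length(wavelength_nm))
    stop("weight must match wavelength_nm in length")
  if (any(weight < 0)) stop("weights must be nonnegative")
  if (sum(weight) <= 0) stop("weights must not all be zero")
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 weight = weight / sum(weight)),
            class = "emission_spectrum")
}

#' Point-spread-function kernel
#'
#' A nonnegative 2D kernel on a square pixel grid, normalized to unit sum,
#' with an explicit center pixel marking zero lateral displacement.
#'
#' @param grid nonnegative numeric matrix
#' @param pixel_pitch_um pixel spacing in micrometres
#' @param center (row, col) index of zero displacement; default middle pixel
#' @param normalize divide by the total sum (default `TRUE`)
#' @param collection_gain light-collection efficiency relative to the plain
#'   scintillator-air interface (1 for hand-made kernels; set by
#'   [build_psf()], where a metasurface that redirects otherwise trapped
#'   light into the acceptance cone earns a gain above 1)
#' @return an object of class `psf_kernel`
#' @export
psf_kernel <- function(grid, pixel_pitch_um = 1, center = NULL,
                       normalize = TRUE, collection_gain = 1) {
  grid <- as.matrix(grid)
  if (any(grid < 0)) stop("kernel entries must be nonnegative")
  if (is.null(center))
    center <- c(default_center(nrow(grid)), default_center(ncol(grid)))
  if (center[1] < 1 || center[1] > nrow(grid) ||
      center[2] < 1 || center[2] > ncol(grid))
    stop("center must lie inside the kernel grid")
  s <- sum(grid)
  if (normalize) {
    if (s <= 0) stop("kernel must have positive total weight")
    grid <- grid / s
  }
  if (collection_gain <= 0) stop("collection_gain must be positive")
  structure(list(grid = grid, pixel_pitch_um = pixel_pitch_um,
                 center = as.integer(center),
                 collection_gain = collection_gain),
            class = "psf_kernel")
}

#' Single-pixel delta kernel
#'
#' @param size odd kernel side length
#' @param pixel_pitch_um pixel spacing in micrometres
#' @export
delta_kernel <- function(size = 1L, pixel_pitch_um = 1) {
  g <- matrix(0, size, size)
  ctr <- default_center(size)
  g[ctr, ctr] <- 1
  psf_kernel(g, pixel_pitch_um)
}

#' Critical angle of total internal reflection
#'
#' Angle (in the medium) beyond which light at a planar interface with air is
#' totally internally reflected: `asin(1 / n)`.
#'
#' @param n_scint refractive index, >= 1
#' @return angle in degrees; 90 at `n_scint = 1`
#' @export
critical_angle <- function(n_scint) {
  if (!is.numeric(n_scint) || any(n_scint < 1))
    stop("n_scint must be >= 1")
  asin(1 / n_scint) * 180 / pi
}

#' Escape-cone fraction of isotropic emission
#'
#' Solid-angle fraction of isotropically emitted light that lies inside the
#' escape cone of one planar exit face: `(1 - cos(theta_c)) / 2`. The
#' complementary fraction `1 - escape_fraction(n)` is trapped by total
#' internal reflection (or leaves through other faces); for Ce:YAG
#' (n = 1.82) the lost fraction rounds to 92 percent.
#'
#' @inheritParams critical_angle
#' @return fraction in `[0, 0.5]`
#' @export
escape_fraction <- function(n_scint) {
  theta_c <- critical_angle(n_scint) * pi / 180
  (1 - cos(theta_c)) / 2
}

#' Exit sine of a transmitted diffraction order
#'
#' Transmission grating equation into air for light hitting the exit face at
#' angle `theta` inside the scintillator:
#' `s = n_scint * sin(theta) - m * lambda / xi`. The order propagates into
#' air iff `|s| < 1`; for `m = 0` this reduces to Snell refraction with total
#' internal reflection beyond the critical angle.
#'
#' @param incidence_deg internal incidence angle theta in degrees
#' @param wavelength_nm vacuum wavelength lambda in nanometres, > 0
#' @param period_nm grating period xi in nanometres, > 0
#' @param m signed diffraction order
#' @param n_scint refractive index of the medium
#' @return the (possibly out-of-range) exit sine; vectorized
#' @export
diffraction_exit_sine <- function(incidence_deg, wavelength_nm, period_nm,
                                  m, n_scint = 1.82) {
  if (any(period_nm <= 0)) stop("period_nm must be positive")
  if (any(wavelength_nm <= 0)) stop("wavelength_nm must be positive")
  n_scint * sin(incidence_deg * pi / 180) - m * wavelength_nm / period_nm
}

#' Diffraction-order table
#'
#' Enumerates every (incidence angle, wavelength, order) combination for a
#' metasurface/system/spectrum and classifies each as propagating (exit sine
#' inside the unit interval) and in-acceptance (propagating with exit angle
#' within the system acceptance half-angle).
#'
#' @param meta a [metasurface()]
#' @param sys an [optical_system()]
#' @param spectrum an [emission_spectrum()]
#' @param theta_grid internal incidence angles in degrees
#' @return a data.frame with columns `theta_deg`, `wavelength_nm`, `order`,
#'   `exit_sine`, `weight_lambda`, `propagating`, `in_acceptance`
#' @export
order_table <- function(meta, sys, spectrum,
                        theta_grid = seq(0, 89, by = 1)) {
  stopifnot(inherits(meta, "metasurface"), inherits(sys, "optical_system"),
            inherits(spectrum, "emission_spectrum"))
  if (length(theta_grid) == 0) stop("theta_grid must be nonempty")
  if (length(spectrum$wavelength_nm) == 0) stop("spectrum must be nonempty")
  orders <- if (meta$geometry == "none") 0L else
    seq.int(-meta$order_range, meta$order_range)
  tab <- expand.grid(theta_deg = theta_grid,
                     wavelength_nm = spectrum$wavelength_nm,
                     order = orders,
                     KEEP.OUT.ATTRS = FALSE)
  period <- if (meta$geometry == "none") Inf else meta$period_nm
  s <- sys$n_scint * sin(tab$theta_deg * pi / 180) -
    ifelse(tab$order == 0, 0, tab$order * tab$wavelength_nm / period)
  tab$exit_sine <- s
  wl <- spectrum$weight[match(tab$wavelength_nm, spectrum$wavelength_nm)]
  tab$weight_lambda <- wl
  tab$propagating <- abs(s) < 1
  exit_deg <- ifelse(tab$propagating, asin(pmin(pmax(s, -1), 1)) * 180 / pi, NA)
  tab$in_acceptance <- tab$propagating &
    abs(exit_deg) <= sys$acceptance_half_angle_deg
  tab
}

# Per-order efficiency lookup.
order_efficiency <- function(meta, m) {
  if (meta$efficiency_model == "uniform_orders") return(rep(1, length(m)))
  eff <- meta$efficiency_table[as.character(m)]
  eff[is.na(eff)] <- 0
  as.numeric(eff)
}

# Order multiplicity: a 1D grating has one reciprocal-lattice point per
# signed order, while an isotropic 2D-periodic structure has the on-axis
# ring of its square reciprocal lattice behind each radial order (4 points
# for m != 0). Diagonal lattice orders are not modeled.
order_multiplicity <- function(meta, m) {
  if (meta$geometry == "isotropic_2d") ifelse(m == 0, 1, 4) else rep(1, length(m))
}

# Total reciprocal-lattice energy split: (2R+1) collinear orders for a 1D
# grating, the full (2R+1)^2 lattice for an isotropic 2D structure.
order_energy_total <- function(meta) {
  orders <- if (meta$geometry == "none") 0L else
    seq.int(-meta$order_range, meta$order_range)
  base <- sum(order_efficiency(meta, orders) * order_multiplicity(meta, orders))
  if (meta$geometry == "isotropic_2d") {
    # add the unmodeled off-axis lattice points at uniform-order weight
    R <- meta$order_range
    n_all <- (2 * R + 1)^2
    n_axis <- 1 + 4 * R
    mean_eff <- base / n_axis
    base + mean_eff * (n_all - n_axis)
  } else base
}

# Angular emission weights on a theta grid (degrees).
theta_weights <- function(theta_grid, theta_weighting) {
  if (is.numeric(theta_weighting)) {
    if (length(theta_weighting) != length(theta_grid))
      stop("numeric theta_weighting must match theta_grid in length")
    w <- theta_weighting
  } else {
    th <- theta_grid * pi / 180
    w <- switch(theta_weighting,
      lambertian = cos(th) * sin(th),
      uniform = rep(1, length(theta_grid)),
      normal = as.numeric(theta_grid == min(theta_grid)),
      stop("unknown theta_weighting '", theta_weighting,
           "' (use 'lambertian', 'uniform', 'normal' or a numeric vector)"))
  }
  if (sum(w) <= 0) stop("theta weights must not all be zero")
  w / sum(w)
}

# Bilinear splat of weights onto a matrix at fractional (row, col) positions.
# Out-of-range corner contributions raise an error upstream (displacement
# checks), so indices are assumed valid here.
splat_bilinear <- function(grid, r, c, w) {
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  ri <- c(r0, r0, r0 + 1, r0 + 1)
  ci <- c(c0, c0 + 1, c0, c0 + 1)
  wi <- c(w * (1 - fr) * (1 - fc), w * (1 - fr) * fc,
          w * fr * (1 - fc), w * fr * fc)
  keep <- wi > 0
  ri <- ri[keep]; ci <- ci[keep]; wi <- wi[keep]
  if (length(wi) == 0) return(grid)
  if (any(ri < 1 | ri > nrow(grid) | ci < 1 | ci > ncol(grid)))
    stop("splat index outside kernel grid")
  lin <- (ci - 1L) * nrow(grid) + ri
  acc <- rowsum(wi, group = lin)
  idx <- as.integer(rownames(acc))
  grid[idx] <- grid[idx] + acc[, 1]
  grid
}

#' Build the incoherent point-spread function of the optical encoder
#'
#' Aggregates every admitted (angle, wavelength, order) ray into a kernel on
#' the detector grid. Each admitted ray deposits
#' `weight(lambda) * weight(theta) * efficiency(m)` at lateral displacement
#' `d = propagation_distance_um * tan(asin(exit_sine))`; a 1D grating deposits
#' symmetrically at both signs of `d` along the kernel's column axis, while an
#' isotropic structure (and the plain interface) spreads the weight over the
#' annulus of radius `|d|`. The result is convolved with the residual system
#' kernel and normalized to unit sum.
#'
#' The kernel's `collection_gain` records how much more emitted light the
#' structure steers into the acceptance cone than the plain interface does
#' under the same emission model: each ray's energy is split across the
#' considered orders in proportion to their efficiencies, and the admitted
#' fraction is referenced to the `geometry = "none"` baseline. A grating that
#' redirects steep (otherwise totally internally reflected) rays into the
#' acceptance cone therefore earns a gain above 1.
#'
#' @inheritParams order_table
#' @param theta_weighting `"lambertian"` (in-medium Lambertian,
#'   proportional to cos(theta) sin(theta)), `"uniform"`, `"normal"`
#'   (all weight at the smallest grid angle), or a numeric weight vector
#' @param grid_shape (rows, cols) of the kernel grid, both odd
#' @param pixel_pitch_um kernel pixel spacing in micrometres
#' @return a [psf_kernel()]
#' @export
build_psf <- function(meta, sys, spectrum = emission_spectrum(),
                      theta_grid = seq(0, 89, by = 1),
                      theta_weighting = "lambertian",
                      grid_shape = c(33, 33), pixel_pitch_um = 1) {
  tab <- order_table(meta, sys, spectrum, theta_grid)
  adm <- tab[tab$in_acceptance, , drop = FALSE]
  wt_all <- theta_weights(theta_grid, theta_weighting)
  # absolute admitted energy fraction: ray energy is split across the
  # reciprocal lattice in proportion to efficiency times multiplicity
  eff_total <- order_energy_total(meta)
  adm_w <- adm$weight_lambda * wt_all[match(adm$theta_deg, theta_grid)] *
    order_efficiency(meta, adm$order) * order_multiplicity(meta, adm$order)
  eff_abs <- sum(adm_w) / eff_total
  # plain-interface reference under the identical emission model
  none_tab <- order_table(metasurface(geometry = "none"), sys, spectrum,
                          theta_grid)
  none_adm <- none_tab[none_tab$in_acceptance, , drop = FALSE]
  eff_none <- sum(none_adm$weight_lambda *
                    wt_all[match(none_adm$theta_deg, theta_grid)])
  gain <- if (eff_none > 0) eff_abs / eff_none else 1
  nrows <- grid_shape[1]; ncols <- grid_shape[2]
  ctr <- c(default_center(nrows), default_center(ncols))
  grid <- matrix(0, nrows, ncols)
  if (nrow(adm) > 0) {
    wt <- theta_weights(theta_grid, theta_weighting)
    w_theta <- wt[match(adm$theta_deg, theta_grid)]
    w <- adm$weight_lambda * w_theta * order_efficiency(meta, adm$order) *
      order_multiplicity(meta, adm$order)
    d_px <- sys$propagation_distance_um * tan(asin(adm$exit_sine)) /
      pixel_pitch_um
    max_d <- max(abs(d_px))
    half <- (min(nrows, ncols) - 1) / 2
    if (max_d > half) {
      need <- 2 * ceiling(max_d) + 1
      stop("maximum ray displacement of ", signif(max_d, 4),
           " px exceeds the kernel grid; grid_shape of at least (",
           need, ", ", need, ") is required")
    }
    keep <- w > 0
    d_px <- d_px[keep]; w <- w[keep]
    if (meta$geometry == "grating_1d") {
      # symmetric emission about the grating normal: both signs of d
      cc <- c(ctr[2] + d_px, ctr[2] - d_px)
      rr <- rep(ctr[1], length(cc))
      grid <- splat_bilinear(grid, rr, cc, rep(w / 2, 2))
    } else {
      # annular average: spread each ray's weight over its exit ring
      rad <- abs(d_px)
      n_az <- pmax(8L, ceiling(2 * pi * rad * 4))
      n_az[rad < 1e-9] <- 1L
      rr <- vector("list", length(rad)); cc <- rr; ww <- rr
      for (i in seq_along(rad)) {
        phi <- (seq_len(n_az[i]) - 0.5) / n_az[i] * 2 * pi
        rr[[i]] <- ctr[1] + rad[i] * sin(phi)
        cc[[i]] <- ctr[2] + rad[i] * cos(phi)
        ww[[i]] <- rep(w[i] / n_az[i], n_az[i])
      }
      grid <- splat_bilinear(grid, unlist(rr), unlist(cc), unlist(ww))
    }
  } else {
    stop("no ray is admitted by the acceptance geometry; ",
         "the kernel would be empty")
  }
  if (!is.null(sys$system_kernel)) {
    grid <- conv2_reflect(grid, sys$system_kernel$grid,
                          center = sys$system_kernel$center)
    grid[grid < 0] <- 0
  }
  psf_kernel(grid, pixel_pitch_um, center = ctr, collection_gain = gain)
}

#' Export an order table as CSV
#'
#' @param tab data.frame from [order_table()]
#' @param path output file
#' @export
write_order_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
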