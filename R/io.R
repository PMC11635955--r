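# Artifact I/O: images as TIFF with a JSON sidecar holding the scale factor
# and provenance, region masks as 8-bit PNG, tables as CSV.

sidecar_path <- function(path) paste0(path, ".json")

write_image_tiff <- function(mat, path, bits = 32L, meta = list()) {
  scale <- max(mat, 1e-300)
  tiff::writeTIFF(pmin(pmax(mat / scale, 0), 1), path,
                  bits.per.sample = bits)
  meta$scale <- scale
  meta$dim <- dim(mat)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

read_image_tiff <- function(path) {
  mat <- tiff::readTIFF(path)
  meta <- list(scale = 1)
  sc <- sidecar_path(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  list(data = mat * meta$scale, meta = meta)
}

#' Save / load a PSF kernel as float TIFF with a JSON sidecar
#'
#' The sidecar records the pixel pitch, the center index, the value scale and
#' any provenance supplied.
#'
#' @param kernel a [psf_kernel()]
#' @param path output `.tif` path
#' @param provenance optional named list stored verbatim in the sidecar
#' @export
write_psf <- function(kernel, path, provenance = NULL) {
  stopifnot(inherits(kernel, "psf_kernel"))
  write_image_tiff(kernel$grid, path,
                   meta = list(type = "psf_kernel",
                               pixel_pitch_um = kernel$pixel_pitch_um,
                               center = kernel$center,
                               collection_gain = kernel$collection_gain,
                               provenance = provenance))
}

#' @rdname write_psf
#' @export
read_psf <- function(path) {
  x <- read_image_tiff(path)
  psf_kernel(x$data, x$meta$pixel_pitch_um,
             center = unlist(x$meta$center), normalize = TRUE,
             collection_gain = if (is.null(x$meta$collection_gain)) 1
                               else x$meta$collection_gain)
}

#' Save / load a captured frame as TIFF with settings sidecar
#'
#' @param shot a [captured_image()]
#' @param path output `.tif` path
#' @export
write_capture <- function(shot, path) {
  stopifnot(inherits(shot, "captured_image"))
  s <- shot$settings
  write_image_tiff(shot$counts, path, bits = 32L,
                   meta = list(type = "captured_image",
                               kernel_id = shot$kernel_id,
                               pixel_pitch_um = shot$pixel_pitch_um,
                               settings = s[setdiff(names(s), "")]))
}

#' @rdname write_capture
#' @export
read_capture <- function(path) {
  x <- read_image_tiff(path)
  s <- x$meta$settings
  settings <- exposure_settings(s$t_cap_ms, s$photons_per_pixel_per_ms,
                                s$read_noise_sd, s$bin_factor, s$seed,
                                isTRUE(s$noiseless))
  captured_image(x$data, settings, x$meta$kernel_id,
                 pixel_pitch_um = x$meta$pixel_pitch_um)
}

#' Save / load a source image (phantom) as TIFF
#'
#' Region masks, when present, are written as 8-bit PNG files next to the
#' image (`<path>.<region>.png`).
#'
#' @param src a [source_image()]
#' @param path output `.tif` path
#' @export
write_phantom <- function(src, path) {
  stopifnot(inherits(src, "source_image"))
  write_image_tiff(src$intensity, path,
                   meta = list(type = "source_image",
                               pixel_pitch_um = src$pixel_pitch_um,
                               regions = names(src$regions)))
  for (nm in names(src$regions)) {
    png_path <- paste0(path, ".", nm, ".png")
    png::writePNG(src$regions[[nm]] * 1, png_path)
  }
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  x <- read_image_tiff(path)
  regions <- NULL
  for (nm in unlist(x$meta$regions)) {
    png_path <- paste0(path, ".", nm, ".png")
    if (file.exists(png_path)) {
      m <- png::readPNG(png_path)
      if (length(dim(m)) == 3) m <- m[, , 1]
      regions[[nm]] <- m > 0.5
    }
  }
  source_image(pmin(pmax(x$data, 0), 1), x$meta$pixel_pitch_um, regions)
}

#' Save a sinogram as float TIFF with geometry sidecar
#'
#' @param sino a [sinogram()]
#' @param path output `.tif` path
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  write_image_tiff(sino$data, path,
                   meta = list(type = "sinogram",
                               angles_deg = sino$angles_deg,
                               detector_pitch_um = sino$detector_pitch_um))
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  x <- read_image_tiff(path)
  sinogram(x$data, unlist(x$meta$angles_deg), x$meta$detector_pitch_um)
}
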