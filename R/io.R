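# File formats: grayscale TIFF/PNG interferograms with YAML sidecar configs,
# 32-bit float TIFF phase maps, and an RDS bundle holding frames together with
# ground truth for tests and round trips.

#' Write an interferogram to TIFF or PNG with a YAML sidecar
#'
#' The image is written at the configured bit depth; the acquisition geometry
#' goes to `<path>.yaml` so the frame can be re-read with its metadata.
#'
#' @param interferogram an interferogram.
#' @param path output file; extension selects the format (`.tif`/`.tiff` or
#'   `.png`).
#' @param sidecar write the YAML sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_interferogram <- function(interferogram, path, sidecar = TRUE) {
  stopifnot(inherits(interferogram, "interferogram"))
  cfg <- interferogram$config
  scale <- 2^cfg$bit_depth - 1
  img <- interferogram$intensity / scale   # [0,1] for the writers
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = cfg$bit_depth)
  } else if (ext == "png") {
    png::writePNG(img, path)  # 8-bit
  } else {
    stop("unsupported image format: .", ext)
  }
  if (sidecar) {
    yaml::write_yaml(c(config_to_list(cfg),
                       list(shear_mm = interferogram$shear_mm,
                            distance_mm = interferogram$distance_mm)),
                     paste0(path, ".yaml"))
  }
  invisible(path)
}

#' Read a grayscale interferogram image
#'
#' Reads TIFF or PNG; a `<path>.yaml` sidecar, when present, restores the
#' acquisition geometry. Without a sidecar a default [acq_config()] matching
#' the image size is attached and the shear is marked unknown (`NA`).
#'
#' @param path image file.
#' @param config optional [acq_config()] overriding any sidecar.
#' @return An interferogram object.
#' @export
read_image <- function(path, config = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    png::readPNG(path)
  } else {
    stop("unsupported image format: .", ext)
  }
  if (length(dim(img)) != 2) stop("not a grayscale image: ", path)
  storage.mode(img) <- "double"
  side <- paste0(path, ".yaml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else NULL
  if (is.null(config)) {
    config <- if (!is.null(meta)) {
      config_from_list(meta, sensor_pixels = nrow(img))
    } else {
      acq_config(sensor_pixels = nrow(img),
                 n_pixels = min(501L, nrow(img)),
                 bit_depth = if (ext == "png") 8L else 16L)
    }
  }
  gray <- if (ext == "png") round(img * (2^config$bit_depth - 1)) else img
  new_interferogram(gray, config,
                    shear_mm = meta$shear_mm %||% NA_real_,
                    distance_mm = meta$distance_mm %||% NA_real_)
}

#' @keywords internal
config_to_list <- function(cfg) {
  list(wavelength_nm = cfg$wavelength_nm,
       grating_pitch_um = cfg$grating_pitch_um,
       beam_size_mm = cfg$beam_size_mm,
       n_pixels = cfg$n_pixels,
       sensor_pixels = cfg$sensor_pixels,
       bit_depth = cfg$bit_depth,
       max_gray = cfg$max_gray,
       refractive_index = cfg$refractive_index)
}

#' @keywords internal
config_from_list <- function(lst, sensor_pixels = NULL) {
  acq_config(wavelength_nm = lst$wavelength_nm %||% 623,
             grating_pitch_um = lst$grating_pitch_um %||% 30,
             beam_size_mm = lst$beam_size_mm %||% 7.066,
             n_pixels = lst$n_pixels %||% 501L,
             sensor_pixels = lst$sensor_pixels %||% sensor_pixels %||% 2048L,
             bit_depth = lst$bit_depth %||% 8L,
             max_gray = lst$max_gray,
             refractive_index = lst$refractive_index %||% 1.457)
}

#' Read or write an acquisition/run configuration as YAML
#'
#' @param path YAML file.
#' @return [read_config()] returns an [acq_config()].
#' @export
read_config <- function(path) config_from_list(yaml::read_yaml(path))

#' @rdname read_config
#' @param config an [acq_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "acq_config"))
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' Write a phase map as 32-bit TIFF
#'
#' The values are stored normalized to [0, 1] at 32-bit precision; the
#' physical range, extent and unit go to the YAML sidecar, so the round trip
#' through [read_phase_tiff()] is lossless to single precision.
#'
#' @param pm a [phase_map()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_phase_tiff <- function(pm, path) {
  stopifnot(inherits(pm, "phase_map"))
  rng <- range(pm$values)
  span <- if (diff(rng) > 0) diff(rng) else 1
  tiff::writeTIFF((pm$values - rng[1]) / span, path, bits.per.sample = 32,
                  reduce = FALSE)
  yaml::write_yaml(list(extent_mm = pm$extent_mm, unit = pm$unit,
                        value_min = rng[1], value_max = rng[2]),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a 32-bit TIFF phase map written by [write_phase_tiff()]
#'
#' @param path `.tif` path with its YAML sidecar.
#' @return A [phase_map()].
#' @export
read_phase_tiff <- function(path) {
  v <- tiff::readTIFF(path)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  span <- meta$value_max - meta$value_min
  phase_map(v * (if (span > 0) span else 1) + meta$value_min,
            meta$extent_mm, meta$unit)
}

#' Bundle simulated frames with their ground truth
#'
#' Writes/reads an RDS archive holding both interferograms and the generating
#' phantom, for reproducible end-to-end tests.
#'
#' @param frame_a,frame_b interferograms of the two arms.
#' @param truth the generating [phase_map()] (optional).
#' @param path `.rds` path.
#' @return [read_bundle()] returns the stored list.
#' @export
write_bundle <- function(frame_a, frame_b, truth = NULL, path) {
  saveRDS(list(frame_a = frame_a, frame_b = frame_b, truth = truth), path)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) readRDS(path)
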