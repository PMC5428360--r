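# Acquisition geometry of a quadriwave lateral shearing interferometer.
#
# The diffractive element produces exactly four first orders (+1/-1 along two
# orthogonal axes). The lateral shear between the interfering replica pair on
# the image plane is s = 2*sqrt(2)*l*lambda/d, where l is the grating-to-sensor
# distance and d the grating pitch, so the shear is tuned continuously by
# moving the grating.

#' Acquisition configuration for a QWLSI arm
#'
#' @param wavelength_nm illumination wavelength (nm). Default 623, the dominant
#'   wavelength of a red LED source.
#' @param grating_pitch_um grating pitch d (um). Default 30, which makes the
#'   sideband crop of a 2048-px sensor yield a 501 x 501 retrieval grid
#'   without zero padding.
#' @param beam_size_mm physical side length of the beam/field on the sensor
#'   (mm). Default 7.066.
#' @param n_pixels retrieval grid size per side (default 501).
#' @param sensor_pixels sensor resolution per side used for rendering and
#'   demodulation (default 2048).
#' @param bit_depth camera bit depth (default 8).
#' @param max_gray saturation gray level; defaults to `2^bit_depth - 1`.
#' @param refractive_index substrate refractive index used for OPD-to-depth
#'   conversion (default 1.457, fused quartz at 623 nm).
#' @return An `acq_config` object.
#' @export
acq_config <- function(wavelength_nm = 623,
                       grating_pitch_um = 30,
                       beam_size_mm = 7.066,
                       n_pixels = 501L,
                       sensor_pixels = 2048L,
                       bit_depth = 8L,
                       max_gray = NULL,
                       refractive_index = 1.457) {
  max_gray <- max_gray %||% (2^bit_depth - 1)
  stopifnot(wavelength_nm > 0, grating_pitch_um > 0, beam_size_mm > 0,
            n_pixels >= 8, sensor_pixels >= n_pixels,
            bit_depth %in% c(8L, 16L), max_gray > 0,
            max_gray <= 2^bit_depth - 1)
  structure(list(wavelength_nm = wavelength_nm,
                 grating_pitch_um = grating_pitch_um,
                 beam_size_mm = beam_size_mm,
                 n_pixels = as.integer(n_pixels),
                 sensor_pixels = as.integer(sensor_pixels),
                 bit_depth = as.integer(bit_depth),
                 max_gray = max_gray,
                 refractive_index = refractive_index),
            class = "acq_config")
}

#' @export
print.acq_config <- function(x, ...) {
  cat(sprintf(paste0("<acq_config> lambda %.1f nm, pitch %.1f um, field %.3f mm,\n",
                     "  sensor %d px -> retrieval %d px, %d-bit (max gray %g), n %.3f\n"),
              x$wavelength_nm, x$grating_pitch_um, x$beam_size_mm,
              x$sensor_pixels, x$n_pixels, x$bit_depth, x$max_gray,
              x$refractive_index))
  invisible(x)
}

#' Lateral shear from grating-to-sensor distance
#'
#' `s = 2 * sqrt(2) * l * lambda / d`. The sqrt(2) reflects the 45-degree
#' orientation of the grating orders relative to its pitch axes.
#'
#' @param distance_mm grating-to-sensor distance l (mm).
#' @param config an [acq_config()].
#' @return Shear s in mm.
#' @export
shear_from_distance <- function(distance_mm, config) {
  if (distance_mm <= 0) stop("grating-to-sensor distance must be positive")
  2 * sqrt(2) * distance_mm * config$wavelength_nm / (config$grating_pitch_um * 1000)
}

#' Grating-to-sensor distance that produces a given shear
#'
#' Inverse of [shear_from_distance()].
#' @param shear_mm lateral shear s (mm).
#' @param config an [acq_config()].
#' @return Distance l in mm.
#' @export
distance_for_shear <- function(shear_mm, config) {
  stopifnot(shear_mm > 0)
  shear_mm * config$grating_pitch_um * 1000 / (2 * sqrt(2) * config$wavelength_nm)
}

#' Shear ratio beta = s / beam size
#' @param shear_mm lateral shear (mm).
#' @param config an [acq_config()].
#' @return Dimensionless ratio in (0, 0.5).
#' @export
shear_ratio <- function(shear_mm, config) {
  beta <- shear_mm / config$beam_size_mm
  if (beta <= 0 || beta >= 0.5) {
    stop(sprintf("shear ratio %.4g outside (0, 0.5): shear too large for the field", beta))
  }
  beta
}

#' Fringe carrier frequency of the quadriwave interferogram
#'
#' The +1/-1 order pair along each axis interferes at twice the single-order
#' tilt, i.e. at `2 * sqrt(2) / d` cycles/mm.
#' @param config an [acq_config()].
#' @return Carrier magnitude in cycles/mm.
#' @export
carrier_frequency <- function(config) {
  2 * sqrt(2) / (config$grating_pitch_um / 1000)
}
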