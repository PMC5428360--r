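# Forward model: render a quadriwave lateral shearing interferogram.
#
# The four grating orders are modelled as unit-amplitude replicas of the field
# exp(i*phi), tilted by +/- the carrier frequency along the sensor x and y
# axes and laterally displaced by +/- s/2 along the same axis. Their mutual
# interference puts the x- and y-direction shearing phases on sidebands at
# twice the single-order carrier. Scalar and monochromatic: the first-order
# achromaticity of the shearing phases makes broadband effects negligible at
# the shears used here.

#' Render a quadriwave lateral shearing interferogram
#'
#' @param phase a [phase_map()] phantom in OPD or phase units.
#' @param config an [acq_config()].
#' @param distance_mm grating-to-sensor distance l (mm); sets the shear via
#'   [shear_from_distance()].
#' @param offset_px length-2 numeric; sub-pixel translation (x, y) of the
#'   recorded frame, emulating inter-camera misalignment or vibration.
#' @param noise `"none"` or `"shot"` (Poisson photon noise).
#' @param mean_max_count Poisson mean at the noiseless intensity maximum.
#'   Default 1000, calibrated so an 8-bit frame peaking at gray 132 shows
#'   frame-to-frame deviations up to roughly 27 gray levels, matching a
#'   photon-starved LED acquisition.
#' @param peak_gray gray level assigned to the noiseless maximum; defaults to
#'   `config$max_gray`.
#' @param seed integer seed for the shot noise (RNG state is restored).
#' @param quantize round to integer gray levels (default `TRUE`). Set to
#'   `FALSE` with `noise = "none"` to keep the continuous noiseless pattern,
#'   e.g. as the base for repeated [add_shot_noise()] draws.
#' @return An `interferogram` object: quantized intensity matrix plus the
#'   geometry that produced it.
#' @export
render_interferogram <- function(phase, config, distance_mm,
                                 offset_px = c(0, 0),
                                 noise = c("none", "shot"),
                                 mean_max_count = 1000,
                                 peak_gray = NULL,
                                 seed = NULL,
                                 quantize = TRUE) {
  noise <- match.arg(noise)
  stopifnot(inherits(phase, "phase_map"), inherits(config, "acq_config"))
  peak_gray <- peak_gray %||% config$max_gray
  if (peak_gray > config$max_gray) stop("peak_gray exceeds saturation")
  s_mm <- shear_from_distance(distance_mm, config)
  if (s_mm >= config$beam_size_mm / 2) {
    stop("shear amounts to half the field or more; reduce the distance")
  }
  n <- config$sensor_pixels
  phi <- convert_unit(resample_phase_map(phase, n), "phase_rad",
                      config$wavelength_nm)$values

  # band-limit check: sideband spread must stay below the carrier separation
  fc_bins <- carrier_frequency(config) * config$beam_size_mm  # cycles per field
  gmax <- max(abs(diff(phi)), abs(t(diff(t(phi)))))
  if (gmax * n / (2 * pi) > 0.5 * fc_bins) {
    warning("phantom is not band-limited below the carrier separation; ",
            "sidebands may overlap")
  }

  s_px <- s_mm / config$beam_size_mm * n
  x01 <- (0:(n - 1)) / n
  # each order is tilted by half the pair separation (sqrt(2)/d); the +1/-1
  # pair then interferes at the full carrier 2*sqrt(2)/d
  ramp <- exp(2i * pi * (fc_bins / 2) * x01)
  ramp_x <- matrix(ramp, n, n, byrow = TRUE)  # varies along columns (x)
  ramp_y <- matrix(ramp, n, n)                # varies along rows (y)

  repl <- fourier_shift_multi(phi, list(c(+s_px / 2, 0), c(-s_px / 2, 0),
                                        c(0, +s_px / 2), c(0, -s_px / 2)))
  field <- ramp_x       * exp(1i * repl[[1]]) +
           Conj(ramp_x) * exp(1i * repl[[2]]) +
           ramp_y       * exp(1i * repl[[3]]) +
           Conj(ramp_y) * exp(1i * repl[[4]])
  intensity <- Mod(field)^2

  if (any(offset_px != 0)) {
    intensity <- pmax(fourier_shift(intensity, offset_px), 0)
  }
  intensity <- intensity / max(intensity)

  gray <- if (noise == "shot") {
    counts <- with_seed(seed,
      matrix(stats::rpois(n^2, intensity * mean_max_count), n, n))
    counts * (peak_gray / mean_max_count)
  } else {
    intensity * peak_gray
  }
  if (quantize) gray <- round_half_away(gray)
  gray <- pmin(pmax(gray, 0), config$max_gray)

  new_interferogram(gray, config, shear_mm = s_mm, distance_mm = distance_mm)
}

#' Add a shot-noise realization to a noiseless interferogram
#'
#' Treats the stored intensity as the noiseless fringe pattern, draws Poisson
#' counts with mean `mean_max_count` at the pattern maximum, and quantizes.
#' Useful for temporal-stability studies where many noise realizations of one
#' scene are needed without re-rendering the optics.
#'
#' @param interferogram a noiseless interferogram (ideally rendered with
#'   `quantize = FALSE`).
#' @param mean_max_count Poisson mean at the intensity maximum (default 1000).
#' @param peak_gray gray level of the noiseless maximum; defaults to the
#'   stored maximum.
#' @param seed integer seed (RNG state restored).
#' @return A new interferogram with one shot-noise realization.
#' @export
add_shot_noise <- function(interferogram, mean_max_count = 1000,
                           peak_gray = NULL, seed = NULL) {
  stopifnot(inherits(interferogram, "interferogram"))
  img <- interferogram$intensity
  peak_gray <- peak_gray %||% max(img)
  n <- nrow(img)
  counts <- with_seed(seed,
    matrix(stats::rpois(n^2, img / max(img) * mean_max_count), n, n))
  gray <- pmin(pmax(round_half_away(counts * (peak_gray / mean_max_count)), 0),
               interferogram$config$max_gray)
  new_interferogram(gray, interferogram$config, interferogram$shear_mm,
                    interferogram$distance_mm)
}

#' @keywords internal
new_interferogram <- function(intensity, config, shear_mm, distance_mm = NA_real_) {
  if (any(intensity < 0) || any(intensity > config$max_gray)) {
    stop("interferogram intensity outside [0, max_gray]")
  }
  structure(list(intensity = intensity, config = config, shear_mm = shear_mm,
                 distance_mm = distance_mm,
                 carrier_cyc_mm = carrier_frequency(config)),
            class = "interferogram")
}

#' @export
print.interferogram <- function(x, ...) {
  cat(sprintf(paste0("<interferogram> %d x %d px, shear %.4g mm (beta %.3g%%),",
                     " carrier %.4g cyc/mm, gray range [%g, %g]\n"),
              nrow(x$intensity), ncol(x$intensity), x$shear_mm,
              100 * x$shear_mm / x$config$beam_size_mm, x$carrier_cyc_mm,
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' @export
plot.interferogram <- function(x, ...) {
  n <- nrow(x$intensity)
  graphics::image(z = t(x$intensity[n:1, ]), col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, useRaster = TRUE, main = "interferogram", ...)
  invisible(x)
}
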