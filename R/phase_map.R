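# phase_map: a square 2D optical field with physical sampling metadata.
# Values are either optical path difference in nanometres ("opd_nm"), phase in
# radians ("phase_rad"), or physical etch depth in nanometres ("depth_nm").

#' Construct a phase map
#'
#' A `phase_map` is a square numeric matrix of optical path difference (nm),
#' phase (rad) or depth (nm), together with the physical side length of the
#' field it samples. Rows index y (downwards), columns index x (rightwards),
#' pixel (1,1) at the top-left.
#'
#' @param values square numeric matrix, all finite, at least 8 x 8.
#' @param extent_mm physical side length of the field in millimetres.
#' @param unit one of `"opd_nm"`, `"phase_rad"`, `"depth_nm"`.
#' @return A `phase_map` object.
#' @export
phase_map <- function(values, extent_mm, unit = c("opd_nm", "phase_rad", "depth_nm")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("phase_map grid must be square")
  if (nrow(values) < 8) stop("phase_map grid must be at least 8 x 8 pixels")
  if (!all(is.finite(values))) stop("phase_map values must all be finite")
  if (!is.numeric(extent_mm) || length(extent_mm) != 1 || extent_mm <= 0) {
    stop("extent_mm must be a positive scalar")
  }
  structure(list(values = values, extent_mm = extent_mm, unit = unit,
                 n_pixels = nrow(values)),
            class = "phase_map")
}

#' @export
as.matrix.phase_map <- function(x, ...) x$values

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %d x %d px, %.4g mm field, unit %s, range [%.4g, %.4g]\n",
              x$n_pixels, x$n_pixels, x$extent_mm, x$unit,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.phase_map <- function(x, main = NULL, ...) {
  graphics::image(z = t(x$values[x$n_pixels:1, ]),
                  x = seq(0, x$extent_mm, length.out = x$n_pixels),
                  y = seq(0, x$extent_mm, length.out = x$n_pixels),
                  col = grDevices::hcl.colors(128, "viridis"),
                  xlab = "x (mm)", ylab = "y (mm)", useRaster = TRUE,
                  main = main %||% sprintf("phase map (%s)", x$unit), ...)
  invisible(x)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a phase map between OPD and phase units
#'
#' OPD is wavelength independent; the conversion to phase is
#' `phi = 2 * pi * OPD / lambda`.
#'
#' @param pm a [phase_map()].
#' @param unit target unit, `"opd_nm"` or `"phase_rad"`.
#' @param wavelength_nm wavelength used for the conversion.
#' @return A `phase_map` in the requested unit.
#' @export
convert_unit <- function(pm, unit, wavelength_nm) {
  stopifnot(inherits(pm, "phase_map"))
  if (pm$unit == unit) return(pm)
  if (pm$unit == "depth_nm" || unit == "depth_nm") {
    stop("use opd_to_depth() for depth conversions")
  }
  v <- if (unit == "phase_rad") {
    pm$values * 2 * pi / wavelength_nm
  } else {
    pm$values * wavelength_nm / (2 * pi)
  }
  phase_map(v, pm$extent_mm, unit)
}

#' Band-limited resampling of a phase map
#'
#' Resamples by cropping or zero-padding the centered Fourier spectrum; exact
#' for fields band-limited below the Nyquist frequency of the coarser grid.
#'
#' @param pm a [phase_map()].
#' @param n_pixels target grid size per side.
#' @return A `phase_map` on the new grid with the same physical extent.
#' @export
resample_phase_map <- function(pm, n_pixels) {
  stopifnot(inherits(pm, "phase_map"))
  n0 <- pm$n_pixels
  if (n_pixels == n0) return(pm)
  s <- fftshift2(fft2(pm$values)) / n0^2
  c0 <- floor(n0 / 2) + 1
  c1 <- floor(n_pixels / 2) + 1
  m <- min(n0, n_pixels)              # size of the spectral block kept
  r0 <- (c0 - floor(m / 2)):(c0 - floor(m / 2) + m - 1)
  r1 <- (c1 - floor(m / 2)):(c1 - floor(m / 2) + m - 1)
  out <- matrix(0 + 0i, n_pixels, n_pixels)
  out[r1, r1] <- s[r0, r0]
  v <- Re(ifft2(ifftshift2(out))) * n_pixels^2
  phase_map(v, pm$extent_mm, pm$unit)
}

#' Remove piston and tilt from a phase map
#'
#' Piston (mean) and tilt (least-squares plane) are unobservable or
#' convention-fixed in shearing interferometry; this removes both.
#'
#' @param pm a [phase_map()] or plain matrix.
#' @return Object of the same type, detilted.
#' @export
remove_piston_tilt <- function(pm) {
  if (inherits(pm, "phase_map")) {
    phase_map(detilt_plane(pm$values)$detilted, pm$extent_mm, pm$unit)
  } else {
    detilt_plane(pm)$detilted
  }
}
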