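# Fourier sideband demodulation: from one quadriwave interferogram to the
# wrapped phases of the x- and y-direction shearing wavefronts.
#
# The spectrum of the interferogram carries the x shearing phase on a sideband
# at (+2*sqrt(2)/d, 0) cycles/mm and the y shearing phase at (0, +2*sqrt(2)/d).
# Cropping a window around each sideband and inverse-transforming the crop
# both removes the carrier and resamples to the retrieval grid: the crop width
# sets the output resolution, so no zero padding is needed.

#' Locate the two sideband carriers of a quadriwave interferogram
#'
#' Finds the dominant spectral magnitude peak of each shearing direction in
#' the closed upper half-plane, outside a DC exclusion zone. A quadriwave
#' interferogram also carries diagonal cross terms between the x and y order
#' pairs; the shearing-phase sidebands are the peaks along the two sensor
#' axes, so the search is restricted to an angular cone around each axis.
#'
#' @param interferogram an interferogram from [render_interferogram()] or
#'   [read_image()].
#' @param dc_exclude_frac radius of the DC exclusion zone as a fraction of the
#'   Nyquist radius (default 0.1).
#' @param min_peak_ratio a peak must exceed this multiple of the median
#'   off-DC magnitude, otherwise demodulation fails (default 10).
#' @param cone_deg half-angle (degrees) of the axis cones searched (default 30).
#' @return List with integer bin offsets from DC, `$x = c(u, v)` and
#'   `$y = c(u, v)`, u along columns, v along rows.
#' @export
locate_carriers <- function(interferogram, dc_exclude_frac = 0.1,
                            min_peak_ratio = 10, cone_deg = 30) {
  stopifnot(inherits(interferogram, "interferogram"))
  img <- interferogram$intensity
  n <- nrow(img)
  a <- Mod(fftshift2(fft2(img - mean(img))))
  kc <- centered_index(n)
  uu <- matrix(kc, n, n, byrow = TRUE)
  vv <- matrix(kc, n, n)
  rr <- sqrt(uu^2 + vv^2)
  cand <- rr > dc_exclude_frac * (n / 2)
  med <- stats::median(a[cand])
  half_rad <- cone_deg * pi / 180
  pick <- function(ok) {
    sel <- which(cand & ok)
    i <- sel[which.max(a[sel])]
    if (a[i] <= min_peak_ratio * med) {
      stop("demodulation failure: no sideband peak above the noise floor")
    }
    c(u = uu[i], v = vv[i])
  }
  # +u axis cone (x shearing direction) and +v axis cone (y direction)
  list(x = pick(uu > 0 & abs(atan2(vv, uu)) <= half_rad),
       y = pick(vv > 0 & abs(atan2(uu, vv)) <= half_rad))
}

#' Extract wrapped shearing phases from a quadriwave interferogram
#'
#' Crops an `out_pixels`-wide block of the centered spectrum around each
#' sideband (translating it to zero frequency, which removes the carrier),
#' applies a circular window, inverse-transforms, and takes the argument.
#'
#' @param interferogram an interferogram.
#' @param carriers carrier bin offsets as returned by [locate_carriers()];
#'   located automatically when `NULL`.
#' @param out_pixels retrieval grid size; defaults to `config$n_pixels`.
#' @param window_frac window radius as a fraction of the carrier radius
#'   (default 0.4), clipped to fit the cropped block.
#' @param taper use a raised-cosine roll-off over the outer 20% of the window
#'   (default `TRUE`); `FALSE` gives a hard circular crop.
#' @param subbin_correction the carrier `2*sqrt(2)/d` generally falls between
#'   frequency bins; when `TRUE` (default) the fractional part known from the
#'   grating geometry is removed from the demodulated phase, which otherwise
#'   leaves a spurious linear ramp in each shearing phase (and hence a
#'   quadratic artifact in the reconstruction). This is the software
#'   equivalent of the carrier calibration done on a real instrument.
#' @return A [shearing_pair()] with wrapped `phi_x`, `phi_y` in (-pi, pi].
#' @export
extract_shearing_phases <- function(interferogram, carriers = NULL,
                                    out_pixels = NULL, window_frac = 0.4,
                                    taper = TRUE, subbin_correction = TRUE) {
  stopifnot(inherits(interferogram, "interferogram"))
  cfg <- interferogram$config
  out_pixels <- out_pixels %||% cfg$n_pixels
  carriers <- carriers %||% locate_carriers(interferogram)
  n <- nrow(interferogram$intensity)
  ctr <- floor(n / 2) + 1
  spec <- fftshift2(fft2(interferogram$intensity))

  sep <- sqrt(sum((carriers$x - carriers$y)^2))
  radius <- function(cb) min(window_frac * sqrt(sum(cb^2)), floor(out_pixels / 2))
  if (max(radius(carriers$x), radius(carriers$y)) >= sep / 2) {
    stop("sideband windows overlap; reduce window_frac")
  }

  # exact carrier position in bins of the sensor grid, from the geometry
  fc_bins <- carrier_frequency(cfg) * cfg$beam_size_mm

  demod_one <- function(cb, axis) {
    r <- radius(cb)
    h <- floor(out_pixels / 2)
    rows <- (ctr + cb["v"] - h):(ctr + cb["v"] - h + out_pixels - 1)
    cols <- (ctr + cb["u"] - h):(ctr + cb["u"] - h + out_pixels - 1)
    if (min(rows, cols) < 1 || max(rows, cols) > n) {
      stop("sideband window clipped by the spectrum edge; ",
           "reduce out_pixels or the carrier frequency")
    }
    block <- spec[rows, cols]
    kb <- centered_index(out_pixels)
    rb <- sqrt(outer(kb^2, kb^2, "+"))
    w <- if (taper) {
      ifelse(rb <= 0.8 * r, 1,
             ifelse(rb <= r, 0.5 * (1 + cos(pi * (rb - 0.8 * r) / (0.2 * r))), 0))
    } else {
      as.numeric(rb <= r)
    }
    field <- ifft2(ifftshift2(block * w))
    if (subbin_correction) {
      # residual fractional carrier left by the integer-bin crop
      eps <- fc_bins * (if (axis == "x") c(1, 0) else c(0, 1)) - cb
      x01 <- (0:(out_pixels - 1)) / out_pixels
      field <- field *
        exp(-2i * pi * eps["u"] * matrix(x01, out_pixels, out_pixels, byrow = TRUE)) *
        exp(-2i * pi * eps["v"] * matrix(x01, out_pixels, out_pixels))
    }
    Arg(field)
  }

  shearing_pair(phi_x = demod_one(carriers$x, "x"),
                phi_y = demod_one(carriers$y, "y"),
                shear_mm = interferogram$shear_mm,
                extent_mm = cfg$beam_size_mm,
                wavelength_nm = cfg$wavelength_nm,
                wrapped = TRUE)
}

#' Shearing-wavefront phase pair
#'
#' Container for the phases of the x- and y-direction shearing wavefronts
#' measured at one lateral shear.
#'
#' @param phi_x,phi_y square phase matrices (rad) of equal size.
#' @param shear_mm the lateral shear s (mm) of this pair.
#' @param extent_mm physical field size (mm).
#' @param wavelength_nm wavelength the phases were measured at.
#' @param wrapped logical; wrapped pairs have all values in (-pi, pi].
#' @return A `shearing_pair` object.
#' @export
shearing_pair <- function(phi_x, phi_y, shear_mm, extent_mm,
                          wavelength_nm = 623, wrapped = TRUE) {
  stopifnot(is.matrix(phi_x), is.matrix(phi_y),
            all(dim(phi_x) == dim(phi_y)), nrow(phi_x) == ncol(phi_x),
            shear_mm > 0, extent_mm > 0)
  if (wrapped && (max(phi_x, phi_y) > pi || min(phi_x, phi_y) <= -pi)) {
    stop("wrapped shearing phases must lie in (-pi, pi]")
  }
  structure(list(phi_x = phi_x, phi_y = phi_y, shear_mm = shear_mm,
                 extent_mm = extent_mm, wavelength_nm = wavelength_nm,
                 wrapped = wrapped, n_pixels = nrow(phi_x)),
            class = "shearing_pair")
}

#' @export
print.shearing_pair <- function(x, ...) {
  cat(sprintf("<shearing_pair> %d x %d px, shear %.4g mm, %s\n",
              x$n_pixels, x$n_pixels, x$shear_mm,
              if (x$wrapped) "wrapped" else "unwrapped"))
  invisible(x)
}

#' Unwrap both phases of a shearing pair with DLPU
#'
#' Convenience wrapper applying [unwrap_dlpu()] to `phi_x` and `phi_y`.
#' @param pair a wrapped [shearing_pair()].
#' @return The pair with unwrapped phases (`wrapped = FALSE`).
#' @export
unwrap_pair <- function(pair) {
  stopifnot(inherits(pair, "shearing_pair"))
  if (!pair$wrapped) return(pair)
  shearing_pair(unwrap_dlpu(pair$phi_x), unwrap_dlpu(pair$phi_y),
                pair$shear_mm, pair$extent_mm, pair$wavelength_nm,
                wrapped = FALSE)
}
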