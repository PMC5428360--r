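# Phase phantoms: deterministic test objects plus a reproducible cell-like
# field. These stand in for the optical bench of a real instrument, so the
# rest of the pipeline can be exercised end to end with known ground truth.

#' One-dimensional sinusoidal phase phantom
#'
#' `W(x, y) = amplitude * sin(2 * pi * x / period_px)`, constant in y. This is
#' the canonical object for sensitivity analysis: a lateral shear of half its
#' period doubles the shearing-wavefront amplitude.
#'
#' @param period_px spatial period in pixels (>= 2).
#' @param amplitude amplitude in radians.
#' @param n_pixels grid size per side.
#' @param extent_mm physical field size (default 7.066 mm).
#' @return A [phase_map()] in `"phase_rad"` units.
#' @export
make_sinusoid_phantom <- function(period_px, amplitude, n_pixels,
                                  extent_mm = 7.066) {
  if (period_px < 2) stop("period_px < 2 would alias on the pixel grid")
  x <- matrix(0:(n_pixels - 1), n_pixels, n_pixels, byrow = TRUE)
  phase_map(amplitude * sin(2 * pi * x / period_px), extent_mm, "phase_rad")
}

#' Etched circular phase target
#'
#' Models a disc of diameter `diameter_um` etched to depth `depth_nm` into a
#' substrate of refractive index `refractive_index`. Etching removes material,
#' so the OPD inside the disc is `-depth_nm * (n - 1)` relative to the
#' background; retrieval compares magnitudes when estimating depth.
#'
#' @param diameter_um disc diameter (um), must fit inside the field.
#' @param depth_nm etching depth (nm).
#' @param refractive_index substrate index n (> 1).
#' @param n_pixels grid size per side.
#' @param extent_um physical field size (um).
#' @param edge_sigma_um optional Gaussian softening of the disc edge (um),
#'   emulating the point-spread function of the imaging system; 0 (default)
#'   keeps the ideal hard edge.
#' @return A [phase_map()] in `"opd_nm"` units.
#' @export
make_disc_phantom <- function(diameter_um, depth_nm, refractive_index = 1.457,
                              n_pixels = 501L, extent_um = 36,
                              edge_sigma_um = 0) {
  if (diameter_um >= extent_um) stop("disc diameter exceeds the field")
  if (refractive_index <= 1) stop("refractive_index must exceed 1")
  cc <- centered_index(n_pixels)
  px_um <- extent_um / n_pixels
  r2 <- outer(cc^2, cc^2, "+") * px_um^2
  v <- matrix(0, n_pixels, n_pixels)
  v[r2 <= (diameter_um / 2)^2] <- -depth_nm * (refractive_index - 1)
  if (edge_sigma_um > 0) {
    # Gaussian PSF applied spectrally (periodic convolution)
    k <- fft_index(n_pixels) / extent_um          # cycles/um
    g <- exp(-2 * (pi * edge_sigma_um)^2 * outer(k^2, k^2, "+"))
    v <- Re(ifft2(fft2(v) * g))
  }
  phase_map(v, extent_um / 1000, "opd_nm")
}

#' Cell-like phase phantom
#'
#' A smooth, band-limited sum of Gaussian and torus-shaped blobs emulating the
#' OPD relief of sparse cells (e.g. the biconcave profile of red blood cells).
#' Fully reproducible from `seed`.
#'
#' @param n_blobs number of blobs (>= 0).
#' @param opd_range_nm length-2 numeric; the final map is scaled so its
#'   maximum OPD lies within this interval (upper bound never exceeded).
#' @param seed integer seed controlling all randomness.
#' @param n_pixels grid size per side.
#' @param extent_mm physical field size (mm).
#' @return A [phase_map()] in `"opd_nm"` units.
#' @export
make_cell_phantom <- function(n_blobs, opd_range_nm = c(0, 300), seed = 1L,
                              n_pixels = 501L, extent_mm = 7.066) {
  stopifnot(n_blobs >= 0, length(opd_range_nm) == 2,
            opd_range_nm[2] >= opd_range_nm[1], opd_range_nm[2] >= 0)
  v <- matrix(0, n_pixels, n_pixels)
  if (n_blobs > 0) {
    v <- with_seed(seed, {
      cc <- centered_index(n_pixels)
      acc <- matrix(0, n_pixels, n_pixels)
      for (b in seq_len(n_blobs)) {
        cx <- stats::runif(1, -0.35, 0.35) * n_pixels
        cy <- stats::runif(1, -0.35, 0.35) * n_pixels
        w  <- stats::runif(1, 0.03, 0.08) * n_pixels   # >= few px: band-limited
        amp <- stats::runif(1, 0.4, 1)
        torus <- stats::runif(1) < 0.5
        r2 <- outer((cc - cy)^2, (cc - cx)^2, "+")
        g <- exp(-r2 / (2 * w^2))
        if (torus) {
          # biconcave profile: ring-weighted Gaussian
          g <- g * (0.35 + r2 / (2 * w^2)) * exp(-r2 / (4 * w^2))
          g <- g / max(g)
        }
        acc <- acc + amp * g
      }
      # super-Gaussian field stop: rolls the blob tails to zero at the edges
      # so the field is effectively periodic for Fourier processing
      renv <- outer(cc^2, cc^2, "+") / (0.46 * n_pixels)^2
      acc * exp(-renv^4)
    })
    peak <- with_seed(seed + 1L,
                      stats::runif(1, opd_range_nm[1], opd_range_nm[2]))
    if (max(v) > 0) v <- v * (peak / max(v))
  }
  phase_map(v, extent_mm, "opd_nm")
}
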