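# Wavefront recovery from unwrapped shearing wavefronts.
#
# In the Fourier domain the shearing operation is multiplicative:
# Fx(u,v) = -2i*sin(pi*s*u) * F(u,v) and Fy likewise in v. Single-shear
# recovery inverts this pair in the least-squares sense; its denominator
# vanishes on the lattice u = m/s, v = n/s, where noise is amplified
# (spectral leaking). Fusing the four spectra of two shears s != s' removes
# every common zero except DC.

#' Spectral transfer factors of the lateral shearing operation
#'
#' Returns the multiplicative factors `-2i*sin(pi*s*u)` and `-2i*sin(pi*s*v)`
#' linking the wavefront spectrum to the x- and y-direction shearing-wavefront
#' spectra.
#'
#' @param u,v spatial frequencies (cycles/mm), any conformable arrays.
#' @param s lateral shear (mm).
#' @return List with complex `hx` and `hy`.
#' @export
shear_transfer <- function(u, v, s) {
  list(hx = -2i * sin(pi * s * u), hy = -2i * sin(pi * s * v))
}

# frequency grids (cycles/mm) in native FFT order for an n-point field
freq_mats <- function(n, extent_mm) {
  k <- fft_index(n) / extent_mm
  list(u = matrix(k, n, n, byrow = TRUE), v = matrix(k, n, n))
}

# shearing phases (rad) -> shearing wavefront spectra (OPD nm)
pair_spectra <- function(pair, wavelength_nm) {
  scale <- wavelength_nm / (2 * pi)
  list(fx = fft2(pair$phi_x * scale), fy = fft2(pair$phi_y * scale))
}

#' Single-shear wavefront reconstruction
#'
#' Recovers the wavefront spectrum as
#' `F = i * (sin(pi*s*u)*Fx + sin(pi*s*v)*Fy) / (2*(sin^2(pi*s*u) + sin^2(pi*s*v)))`
#' and inverse-transforms. Frequency bins whose denominator falls below
#' `eps` times its maximum are zeroed and counted: these are the
#' spectral-leak bins of the shear lattice.
#'
#' @param pair an unwrapped [shearing_pair()].
#' @param config an [acq_config()]; supplies the wavelength that converts the
#'   shearing phases to OPD.
#' @param eps relative regularization threshold (default 1e-6).
#' @return A [phase_map()] in `"opd_nm"` units, piston removed, with
#'   attribute `suppressed_bins` (count of zeroed non-DC bins).
#' @export
reconstruct_single <- function(pair, config, eps = 1e-6) {
  stopifnot(inherits(pair, "shearing_pair"))
  if (pair$wrapped) stop("shearing pair must be unwrapped first (see unwrap_pair)")
  n <- pair$n_pixels
  fr <- freq_mats(n, pair$extent_mm)
  su <- sin(pi * pair$shear_mm * fr$u)
  sv <- sin(pi * pair$shear_mm * fr$v)
  sp <- pair_spectra(pair, config$wavelength_nm)
  den <- 2 * (su^2 + sv^2)
  supp <- den < eps * max(den)
  den[supp] <- 1
  f <- 1i * (su * sp$fx + sv * sp$fy) / den
  f[supp] <- 0
  w <- Re(ifft2(f))
  out <- phase_map(w - mean(w), pair$extent_mm, "opd_nm")
  attr(out, "suppressed_bins") <- sum(supp) - 1L  # DC always suppressed
  out
}

#' Dual-shear least-squares wavefront reconstruction
#'
#' Per-frequency least-squares fusion of the four shearing-wavefront spectra
#' observed at shears s and s':
#' `F = i * sum_k w_k * sin_k * F_k / (2 * sum_k w_k * sin_k^2)`,
#' the unweighted form matching the single-shear formula when the shears
#' coincide. For shear pairs whose zero lattices share no point but DC, the
#' denominator vanishes only at DC and the spectral-leak artifact of
#' single-shear recovery is eliminated.
#'
#' @param pair_a,pair_b unwrapped [shearing_pair()]s on the same grid and
#'   field, with different shears.
#' @param config an [acq_config()].
#' @param weights length-2 positive weights for the two arms (equal-noise
#'   default `c(1, 1)`; raise one for unequal exposure).
#' @param eps relative regularization threshold (default 1e-6).
#' @return A [phase_map()] in `"opd_nm"` units, piston removed, with
#'   attribute `suppressed_bins`.
#' @export
reconstruct_dual <- function(pair_a, pair_b, config, weights = c(1, 1),
                             eps = 1e-6) {
  stopifnot(inherits(pair_a, "shearing_pair"), inherits(pair_b, "shearing_pair"),
            pair_a$n_pixels == pair_b$n_pixels,
            isTRUE(all.equal(pair_a$extent_mm, pair_b$extent_mm)),
            length(weights) == 2, all(weights > 0))
  if (pair_a$wrapped || pair_b$wrapped) {
    stop("shearing pairs must be unwrapped first (see unwrap_pair)")
  }
  if (isTRUE(all.equal(pair_a$shear_mm, pair_b$shear_mm))) {
    warning("equal shears: dual reconstruction degenerates to single-shear behavior")
  }
  n <- pair_a$n_pixels
  fr <- freq_mats(n, pair_a$extent_mm)
  sua <- sin(pi * pair_a$shear_mm * fr$u); sva <- sin(pi * pair_a$shear_mm * fr$v)
  sub <- sin(pi * pair_b$shear_mm * fr$u); svb <- sin(pi * pair_b$shear_mm * fr$v)
  sa <- pair_spectra(pair_a, config$wavelength_nm)
  sb <- pair_spectra(pair_b, config$wavelength_nm)
  den <- 2 * (weights[1] * (sua^2 + sva^2) + weights[2] * (sub^2 + svb^2))
  supp <- den < eps * max(den)
  den[supp] <- 1
  f <- 1i * (weights[1] * (sua * sa$fx + sva * sa$fy) +
             weights[2] * (sub * sb$fx + svb * sb$fy)) / den
  f[supp] <- 0
  w <- Re(ifft2(f))
  out <- phase_map(w - mean(w), pair_a$extent_mm, "opd_nm")
  attr(out, "suppressed_bins") <- sum(supp) - 1L
  out
}

#' Convert optical path difference to etch depth
#'
#' `z = OPD / (n - 1)` for a feature etched into (or deposited on) a substrate
#' of refractive index n measured in transmission.
#'
#' @param opd a [phase_map()] in `"opd_nm"` units.
#' @param refractive_index substrate index n, must exceed 1.
#' @return A [phase_map()] in `"depth_nm"` units.
#' @export
opd_to_depth <- function(opd, refractive_index) {
  stopifnot(inherits(opd, "phase_map"), opd$unit == "opd_nm")
  if (refractive_index <= 1) stop("refractive_index must exceed 1")
  phase_map(opd$values / (refractive_index - 1), opd$extent_mm, "depth_nm")
}

#' Subtract a stored background phase image
#'
#' Removes the systematic wavefront distortion of the probe by subtracting a
#' background measurement taken without the specimen; piston is re-removed.
#'
#' @param measured,background [phase_map()]s on the same grid with the same
#'   unit.
#' @return A [phase_map()]: `measured - background`, zero mean.
#' @export
subtract_background <- function(measured, background) {
  stopifnot(inherits(measured, "phase_map"), inherits(background, "phase_map"))
  if (measured$n_pixels != background$n_pixels) {
    stop("measured and background grids differ in size")
  }
  if (measured$unit != background$unit) stop("unit mismatch")
  v <- measured$values - background$values
  phase_map(v - mean(v), measured$extent_mm, measured$unit)
}
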