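# Differential leveling phase unwrapping (DLPU).
#
# A path-independent unwrapper built entirely from element-wise operations and
# FFTs: (1) forward-difference the wrapped phase along x and y; (2) "level"
# the differentials by re-wrapping them into (-pi, pi], which restores the
# true differentials wherever the underlying gradient is below pi/pixel;
# (3) integrate the leveled differentials in the Fourier domain (the discrete
# least-squares shearing retrieval with a one-pixel shear) into a reference
# phase; (4) round the per-pixel difference between reference and wrapped
# phase to an integer number of 2*pi jumps and add them back. The output is
# congruent to the input modulo 2*pi at every pixel, by construction.
#
# Forward differences are taken periodically (wrap-around at the last
# row/column) so the Fourier integration is self-consistent; the reference is
# only used through a per-pixel rounding, so edge artifacts rarely change the
# jump count. Genuine phase residues (e.g. from heavy noise) have no special
# handling: on residue-free inputs with true gradients below pi/pixel the
# recovery is exact up to a global 2*pi multiple, elsewhere it is best effort.

#' Periodic forward differences of a phase grid
#'
#' @param wrapped numeric matrix (typically a wrapped phase in (-pi, pi]).
#' @return List with `dx` (along columns/x) and `dy` (along rows/y); the last
#'   column/row holds the wrap-around difference.
#' @export
phase_differentials <- function(wrapped) {
  stopifnot(is.matrix(wrapped), nrow(wrapped) >= 2, ncol(wrapped) >= 2,
            all(is.finite(wrapped)))
  n2 <- ncol(wrapped); n1 <- nrow(wrapped)
  list(dx = wrapped[, c(2:n2, 1)] - wrapped,
       dy = wrapped[c(2:n1, 1), ] - wrapped)
}

#' Level phase differentials
#'
#' Raw differentials of a wrapped phase lie in (-2*pi, 2*pi); pixels that
#' crossed a wrap carry a spurious +/- 2*pi offset. Leveling re-wraps each
#' value into (-pi, pi], which equals the true differential wherever the true
#' gradient magnitude is below pi/pixel.
#'
#' @param diff_map numeric matrix of raw differentials.
#' @return Matrix of leveled differentials in (-pi, pi].
#' @export
level_differentials <- function(diff_map) wrap_phase(diff_map)

#' Reference phase from leveled differentials
#'
#' Least-squares integration of the two difference fields in the Fourier
#' domain. With `H = exp(2i*pi*k/N) - 1` the transfer of a periodic forward
#' difference, the spectrum of the reference is
#' `(Conj(Hx)*Dx + Conj(Hy)*Dy) / (|Hx|^2 + |Hy|^2)` with the DC bin set to
#' zero (piston is unobservable). The result is exact for difference fields
#' that are consistent periodic forward differences of some phase.
#'
#' @param leveled_dx,leveled_dy difference matrices of equal size.
#' @return Numeric matrix: the integrated (reference) phase, zero mean.
#' @export
dlpu_reference <- function(leveled_dx, leveled_dy) {
  stopifnot(all(dim(leveled_dx) == dim(leveled_dy)))
  n1 <- nrow(leveled_dx); n2 <- ncol(leveled_dx)
  hx <- matrix(exp(2i * pi * (0:(n2 - 1)) / n2) - 1, n1, n2, byrow = TRUE)
  hy <- matrix(exp(2i * pi * (0:(n1 - 1)) / n1) - 1, n1, n2)
  num <- Conj(hx) * fft2(leveled_dx) + Conj(hy) * fft2(leveled_dy)
  den <- Mod(hx)^2 + Mod(hy)^2
  den[1, 1] <- 1
  num[1, 1] <- 0
  Re(ifft2(num / den))
}

#' Differential leveling phase unwrapping
#'
#' @param wrapped numeric matrix with values in (-pi, pi] (or a `phase_map`
#'   in `"phase_rad"` units, returned as the same type).
#' @param mask optional logical matrix marking valid pixels; used only for the
#'   tilt fits.
#' @return The unwrapped phase; `unwrap_dlpu(w) - w` is an integer multiple of
#'   2*pi at every pixel.
#' @export
unwrap_dlpu <- function(wrapped, mask = NULL) {
  if (inherits(wrapped, "phase_map")) {
    stopifnot(wrapped$unit == "phase_rad")
    return(phase_map(unwrap_dlpu(wrapped$values, mask), wrapped$extent_mm,
                     "phase_rad"))
  }
  stopifnot(is.matrix(wrapped), all(is.finite(wrapped)))
  if (max(wrapped) > pi + 1e-9 || min(wrapped) <= -pi - 1e-9) {
    stop("input must be a wrapped phase in (-pi, pi]")
  }
  d <- phase_differentials(wrapped)
  ref <- dlpu_reference(level_differentials(d$dx), level_differentials(d$dy))
  w_dt <- detilt_plane(wrapped, mask)$detilted
  r_dt <- detilt_plane(ref, mask)$detilted
  k <- round_half_away((r_dt - w_dt) / (2 * pi))
  wrapped + 2 * pi * k
}
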