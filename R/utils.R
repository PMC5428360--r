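# Shared numeric helpers: FFT grids, shifts, plane fits, seeded RNG.

#' @keywords internal
fft2 <- function(x) stats::fft(x)

#' @keywords internal
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Centered integer frequency indices for an N-point DFT
#'
#' For odd N the axis is symmetric, -(N-1)/2 .. (N-1)/2, with a single DC bin.
#' @keywords internal
centered_index <- function(n) seq_len(n) - 1L - floor(n / 2)

#' DFT frequency indices in native (unshifted) FFT order
#' @keywords internal
fft_index <- function(n) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k
}

#' @keywords internal
shift_idx <- function(n, by) ((seq_len(n) - 1 + by) %% n) + 1

#' Move DC (index 1) to the centre bin floor(n/2)+1
#' @keywords internal
fftshift2 <- function(x) {
  x[shift_idx(nrow(x), ceiling(nrow(x) / 2)), shift_idx(ncol(x), ceiling(ncol(x) / 2)), drop = FALSE]
}

#' Inverse of [fftshift2()]
#' @keywords internal
ifftshift2 <- function(x) {
  x[shift_idx(nrow(x), floor(nrow(x) / 2)), shift_idx(ncol(x), floor(ncol(x) / 2)), drop = FALSE]
}

#' Sub-pixel translation of a real field by Fourier phase ramp
#'
#' @param x numeric matrix
#' @param shift_px c(dx, dy) in pixels; dx moves the pattern toward larger
#'   column index, dy toward larger row index (top-left origin).
#' @keywords internal
fourier_shift <- function(x, shift_px) {
  fourier_shift_multi(x, list(shift_px))[[1]]
}

#' Translate one field by several sub-pixel shifts sharing one forward FFT
#' @keywords internal
fourier_shift_multi <- function(x, shifts) {
  if (all(shifts_zero <- vapply(shifts, function(s) all(s == 0), logical(1))) ||
      max(x) == min(x)) {
    return(lapply(shifts, function(s) x))
  }
  n1 <- nrow(x); n2 <- ncol(x)
  kr <- fft_index(n1) / n1
  kc <- fft_index(n2) / n2
  fx <- fft2(x)
  lapply(seq_along(shifts), function(i) {
    if (shifts_zero[i]) return(x)
    s <- shifts[[i]]
    ramp <- exp(-2i * pi * (outer(kr * s[2], kc * s[1], "+")))
    Re(ifft2(fx * ramp))
  })
}

#' Least-squares plane fit and removal
#'
#' Fits piston + tilt over the grid (optionally masked) and returns the
#' detilted field together with the fitted coefficients (per-pixel slopes).
#' @keywords internal
detilt_plane <- function(m, mask = NULL) {
  n1 <- nrow(m); n2 <- ncol(m)
  # mean-centred coordinates keep piston and tilt orthogonal on any grid
  xc <- matrix(0:(n2 - 1) - (n2 - 1) / 2, n1, n2, byrow = TRUE)
  yc <- matrix(0:(n1 - 1) - (n1 - 1) / 2, n1, n2)
  if (is.null(mask)) {
    # centered full grid: orthogonal design, closed form
    ax <- sum(m * xc) / sum(xc^2)
    ay <- sum(m * yc) / sum(yc^2)
    p  <- mean(m)
  } else {
    sel <- which(mask)
    X <- cbind(1, xc[sel], yc[sel])
    beta <- solve(crossprod(X), crossprod(X, m[sel]))
    p <- beta[1]; ax <- beta[2]; ay <- beta[3]
  }
  plane <- p + ax * xc + ay * yc
  list(detilted = m - plane, plane = plane,
       coef = c(piston = p, slope_x = ax, slope_y = ay))
}

#' Round half away from zero (reproducible tie handling)
#' @keywords internal
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Wrap values into (-pi, pi]
#' @keywords internal
wrap_phase <- function(x) pi - ((pi - x) %% (2 * pi))

#' Evaluate an expression with a locally seeded RNG
#'
#' Restores the caller's RNG state afterwards; seed = NULL leaves the global
#' stream untouched.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' @keywords internal
rms <- function(x) sqrt(mean(x^2))
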