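# Spectral sensitivity engine.
#
# The sensitivity of a QWLSI relative to an interferometer with external
# reference is sigma(u,v) = 2*sqrt(sin^2(pi*s*u) + sin^2(pi*s*v)): the signal
# is amplified by up to 2*sqrt(2) while the shot noise is not duplicated.
# With two shears the dual sensitivity sigma'(u,v) =
# sqrt(2)*sqrt(sin^2(pi*s*u)+sin^2(pi*s*v)+sin^2(pi*s'*u)+sin^2(pi*s'*v))
# accounts for the sqrt(2) shot-noise increase of splitting the beam. On the
# discrete grid u = k/extent the products s*u reduce to beta*k, so sensitivity
# maps depend only on the shear ratios beta = s/beam and the grid size.

sens_map <- function(values, beta, extent_mm, n_pixels) {
  structure(list(values = values, beta = beta, extent_mm = extent_mm,
                 n_pixels = n_pixels),
            class = "sensitivity_map")
}

#' @export
print.sensitivity_map <- function(x, ...) {
  cat(sprintf("<sensitivity_map> %d x %d bins, beta = %s, mean %.4g, max %.4g\n",
              x$n_pixels, x$n_pixels,
              paste(sprintf("%.3g%%", 100 * x$beta), collapse = ", "),
              mean(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.sensitivity_map <- function(x, ...) {
  k <- centered_index(x$n_pixels) / x$extent_mm
  graphics::image(x = k, y = k, z = t(x$values), col = grDevices::hcl.colors(128),
                  xlab = "u (cycles/mm)", ylab = "v (cycles/mm)",
                  useRaster = TRUE, main = "spectral relative sensitivity", ...)
  invisible(x)
}

#' Single-shear spectral sensitivity map
#'
#' Evaluates `sigma(u, v) = 2*sqrt(sin^2(pi*s*u) + sin^2(pi*s*v))` on the
#' centered discrete frequency grid `u = k/extent`, k = -(N-1)/2 .. (N-1)/2.
#'
#' @param beta shear ratio s/beam in (0, 0.5).
#' @param extent_mm field size (default 7.066 mm).
#' @param n_pixels grid size (default 501).
#' @return A `sensitivity_map`; values lie in [0, 2*sqrt(2)], 0 at DC.
#' @export
sigma_single <- function(beta, extent_mm = 7.066, n_pixels = 501L) {
  stopifnot(beta > 0, beta < 0.5)
  a <- sin(pi * beta * centered_index(n_pixels))^2
  sens_map(2 * sqrt(outer(a, a, "+")), beta, extent_mm, as.integer(n_pixels))
}

#' Dual-shear spectral sensitivity map
#'
#' Evaluates
#' `sigma'(u,v) = sqrt(2)*sqrt(sin^2(pi*s*u)+sin^2(pi*s*v)+sin^2(pi*s'*u)+sin^2(pi*s'*v))`
#' on the same grid as [sigma_single()].
#'
#' @param beta_a,beta_b shear ratios of the two arms, each in (0, 0.5).
#' @inheritParams sigma_single
#' @return A `sensitivity_map`; values lie in [0, 4], 0 at DC.
#' @export
sigma_dual <- function(beta_a, beta_b, extent_mm = 7.066, n_pixels = 501L) {
  stopifnot(beta_a > 0, beta_a < 0.5, beta_b > 0, beta_b < 0.5)
  k <- centered_index(n_pixels)
  g <- sin(pi * beta_a * k)^2 + sin(pi * beta_b * k)^2
  sens_map(sqrt(2) * sqrt(outer(g, g, "+")), c(beta_a, beta_b), extent_mm,
           as.integer(n_pixels))
}

#' Count the zero bins of a sensitivity map
#'
#' @param map a `sensitivity_map`.
#' @param tol bins with sensitivity below `tol` count as zeros (default 1e-9,
#'   far below any genuine nonzero of the sine lattice at these grids).
#' @return Integer count; 1 means only the DC bin vanishes.
#' @export
count_zero_bins <- function(map, tol = 1e-9) {
  stopifnot(inherits(map, "sensitivity_map"))
  sum(map$values < tol)
}

#' Measurement uncertainty of a QWLSI relative to an externally referenced
#' interferometer
#'
#' `Delta/Delta_0 = 1 / sigma(u, v)`; at the odd half-lattice frequencies
#' `u = (2m+1)/(2s), v = (2n+1)/(2s)` this reaches its minimum `1/(2*sqrt(2))`.
#'
#' @param u,v spatial frequencies (cycles/mm).
#' @param s lateral shear (mm).
#' @return The uncertainty ratio; `Inf` (with a warning) on the zero lattice
#'   where the shear transfer vanishes.
#' @export
uncertainty_ratio <- function(u, v, s) {
  sigma <- 2 * sqrt(sin(pi * s * u)^2 + sin(pi * s * v)^2)
  on_lattice <- sigma < 1e-9   # numerically on the zero lattice
  if (any(on_lattice)) {
    warning("frequency on the shear zero lattice: uncertainty is unbounded")
    sigma[on_lattice] <- 0
  }
  1 / sigma
}

#' Standard deviation of the dual-shear sensitivity over shear-ratio pairs
#'
#' For each pair (beta_a, beta_b) on a square grid, computes the population
#' standard deviation of the sigma' map over all frequency bins. Flat
#' sensitivity (low SD) is the selection criterion for a wideband-enhancing
#' shear pair: the map has a ridge on its diagonal (equal shears, periodic
#' zeros) flanked by two valleys of favorable pairs.
#'
#' @param beta_min,beta_max range of shear ratios (defaults 1% and 3%).
#' @param n_steps grid resolution per axis (default 101).
#' @param extent_mm,n_pixels frequency grid, as in [sigma_single()].
#' @param exclude_dc drop the DC bin from the SD (default `FALSE`: the zero at
#'   DC is part of the distribution).
#' @return An `sd_map` object: matrix of SD values with the beta grid as
#'   dimnames and attributes `beta` (grid) and `exclude_dc`.
#' @export
sd_map <- function(beta_min = 0.01, beta_max = 0.03, n_steps = 101L,
                   extent_mm = 7.066, n_pixels = 501L, exclude_dc = FALSE) {
  rng <- sort(c(beta_min, beta_max))
  stopifnot(rng[1] > 0, rng[2] < 0.5, n_steps >= 2)
  betas <- seq(rng[1], rng[2], length.out = n_steps)
  k <- centered_index(n_pixels)
  dc <- floor(n_pixels / 2) * (n_pixels + 1) + 1  # linear index of DC bin
  a <- lapply(betas, function(b) sin(pi * b * k)^2)
  out <- matrix(NA_real_, n_steps, n_steps,
                dimnames = list(sprintf("%.6g", betas), sprintf("%.6g", betas)))
  nb <- n_pixels^2 - as.integer(exclude_dc)
  for (i in seq_len(n_steps)) {
    for (j in i:n_steps) {
      g <- a[[i]] + a[[j]]
      s2 <- 2 * outer(g, g, "+")   # sigma'^2
      s1 <- sqrt(s2)
      if (exclude_dc) { s1 <- s1[-dc]; s2 <- s2[-dc] }
      sd <- sqrt(max(sum(s2) / nb - (sum(s1) / nb)^2, 0))
      out[i, j] <- sd
      out[j, i] <- sd
    }
  }
  structure(out, beta = betas, exclude_dc = exclude_dc, class = c("sd_map", "matrix"))
}

#' @export
plot.sd_map <- function(x, ...) {
  b <- attr(x, "beta")
  graphics::image(x = 100 * b, y = 100 * b, z = unclass(x),
                  col = grDevices::hcl.colors(128, "inferno"),
                  xlab = "beta (%)", ylab = "beta' (%)", useRaster = TRUE,
                  main = "SD of spectral sensitivity", ...)
  invisible(x)
}

#' Select the optimal lateral shear pair
#'
#' Exhaustive search of the [sd_map()] grid for the off-diagonal pair with the
#' minimum sensitivity SD, subject to a minimum separation between the two
#' ratios. Ties break toward the smaller first ratio, then the smaller second.
#'
#' @inheritParams sd_map
#' @param min_separation smallest allowed |beta_a - beta_b|; defaults to one
#'   grid step (which excludes exactly the diagonal).
#' @return Named numeric `c(beta_a, beta_b)` with `beta_a < beta_b`, carrying
#'   the achieved SD as attribute `sd`.
#' @export
optimize_shear_pair <- function(beta_min = 0.01, beta_max = 0.03,
                                n_steps = 101L, extent_mm = 7.066,
                                n_pixels = 501L, min_separation = NULL) {
  m <- sd_map(beta_min, beta_max, n_steps, extent_mm, n_pixels)
  betas <- attr(m, "beta")
  step <- betas[2] - betas[1]
  min_separation <- min_separation %||% step
  sep <- abs(outer(betas, betas, "-"))
  feasible <- sep >= min_separation - 1e-12
  if (!any(feasible)) stop("no feasible shear pair: min_separation too large")
  vals <- ifelse(feasible, unclass(m), Inf)
  best <- min(vals)
  hits <- which(vals <= best + 1e-15, arr.ind = TRUE)
  # ties toward smaller beta_a then smaller beta_b (symmetric map: sort each)
  cand <- cbind(pmin(betas[hits[, 1]], betas[hits[, 2]]),
                pmax(betas[hits[, 1]], betas[hits[, 2]]))
  ord <- order(cand[, 1], cand[, 2])
  structure(c(beta_a = cand[ord[1], 1], beta_b = cand[ord[1], 2]), sd = best)
}

#' Inter-arm translational offset from binarized centroids
#'
#' Binarizes both phase maps at a fraction of their own maximum magnitude and
#' returns the centroid displacement of map B relative to map A, in pixels.
#' This is the alignment/vibration diagnostic for a dual-arm instrument.
#'
#' @param phase_a,phase_b [phase_map()]s (or matrices) containing a compact
#'   object.
#' @param threshold binarization level as a fraction of each map's maximum
#'   magnitude (default 0.5).
#' @return Named numeric `c(dx, dy)`: centroid(B) - centroid(A) in pixels.
#' @export
estimate_offset <- function(phase_a, phase_b, threshold = 0.5) {
  grab <- function(p) if (inherits(p, "phase_map")) abs(p$values) else abs(p)
  centroid <- function(v) {
    if (max(v) == 0) stop("empty foreground after binarization: blank image")
    fg <- v >= threshold * max(v)
    idx <- which(fg, arr.ind = TRUE)
    ctr <- c(x = mean(idx[, 2]), y = mean(idx[, 1]))
    # a filled compact object of this pixel count has RMS centroid distance
    # ~ sqrt(count/(2*pi)); scattered noise foreground is far more spread out
    rmsd <- sqrt(mean((idx[, 2] - ctr["x"])^2 + (idx[, 1] - ctr["y"])^2))
    if (rmsd > 2 * sqrt(nrow(idx) / (2 * pi))) {
      stop("no compact foreground object after binarization")
    }
    ctr
  }
  ca <- centroid(grab(phase_a))
  cb <- centroid(grab(phase_b))
  c(dx = unname(cb["x"] - ca["x"]), dy = unname(cb["y"] - ca["y"]))
}
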