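# Simulation studies: temporal noise propagation through the dual-shear
# pipeline, and the sensitivity of the reconstruction to inter-arm
# translational offset.

#' Temporal-stability study of dual-shear retrieval under shot noise
#'
#' Renders one noiseless interferogram per arm, draws `n_frames` independent
#' shot-noise realizations of each, runs demodulation, DLPU unwrapping and
#' dual-shear reconstruction on every frame pair, and compares the per-pixel
#' temporal standard deviation of the reconstructed wavefront phase with that
#' of the four unwrapped shearing-wavefront phases.
#'
#' The returned `sd_ratio` is the pixel-mean temporal SD of the reconstruction
#' divided by the pixel-mean temporal SD of the shearing phases. For white
#' shot noise the expected value is
#' `sqrt(mean over the demodulation window of 1/(2*sigma'(u,v)^2))`, about
#' 0.39 at the (1.88%, 1.57%) shear pair; the reciprocal mean sensitivity
#' `1/mean(sigma') ~ 0.5` is the corresponding first-order heuristic.
#'
#' @param beta_a,beta_b shear ratios of the two arms (defaults 1.88%, 1.57%,
#'   the wideband-optimal pair for the 7.066 mm / 501 px sampling).
#' @param n_frames number of shot-noise realizations (default 50).
#' @param config an [acq_config()]; default: 8-bit, 2048-px sensor, 501-px
#'   retrieval.
#' @param phantom [phase_map()] under test; default: flat (background) field.
#' @param mean_max_count Poisson mean at the fringe maximum (default 1000).
#' @param peak_gray gray level at the noiseless maximum (default 132: a
#'   photon-starved 8-bit acquisition).
#' @param seed integer seed; frame f uses `seed + f` per arm.
#' @return List: `sd_shear_rad` (pixel-mean temporal SD of the four unwrapped
#'   shearing phases), `sd_recon_rad` (same for the reconstructed phase),
#'   `sd_ratio`, `n_frames`, and `theory_ratio` (the white-noise prediction
#'   from the sensitivity map).
#' @export
temporal_sd_study <- function(beta_a = 0.0188, beta_b = 0.0157, n_frames = 50,
                              config = acq_config(), phantom = NULL,
                              mean_max_count = 1000, peak_gray = 132,
                              seed = 1L) {
  stopifnot(n_frames >= 2)
  phantom <- phantom %||%
    phase_map(matrix(0, config$n_pixels, config$n_pixels),
              config$beam_size_mm, "opd_nm")
  l_a <- distance_for_shear(beta_a * config$beam_size_mm, config)
  l_b <- distance_for_shear(beta_b * config$beam_size_mm, config)
  base_a <- render_interferogram(phantom, config, l_a, quantize = FALSE,
                                 peak_gray = peak_gray)
  base_b <- render_interferogram(phantom, config, l_b, quantize = FALSE,
                                 peak_gray = peak_gray)
  carriers_a <- locate_carriers(base_a)
  carriers_b <- locate_carriers(base_b)

  n <- config$n_pixels
  acc <- function() list(s = matrix(0, n, n), s2 = matrix(0, n, n))
  push <- function(a, x) { a$s <- a$s + x; a$s2 <- a$s2 + x^2; a }
  shear_acc <- replicate(4, acc(), simplify = FALSE)
  rec_acc <- acc()
  to_rad <- 2 * pi / config$wavelength_nm

  for (f in seq_len(n_frames)) {
    fa <- add_shot_noise(base_a, mean_max_count, peak_gray, seed = seed + f)
    fb <- add_shot_noise(base_b, mean_max_count, peak_gray,
                         seed = seed + n_frames + f)
    ua <- unwrap_pair(extract_shearing_phases(fa, carriers_a))
    ub <- unwrap_pair(extract_shearing_phases(fb, carriers_b))
    rec <- suppressWarnings(reconstruct_dual(ua, ub, config))
    shear_acc[[1]] <- push(shear_acc[[1]], ua$phi_x)
    shear_acc[[2]] <- push(shear_acc[[2]], ua$phi_y)
    shear_acc[[3]] <- push(shear_acc[[3]], ub$phi_x)
    shear_acc[[4]] <- push(shear_acc[[4]], ub$phi_y)
    rec_acc <- push(rec_acc, rec$values * to_rad)
  }

  pix_sd <- function(a) {
    v <- pmax(a$s2 / n_frames - (a$s / n_frames)^2, 0) * n_frames / (n_frames - 1)
    sqrt(v)
  }
  sd_shear <- mean(vapply(shear_acc, function(a) mean(pix_sd(a)), numeric(1)))
  sd_rec <- mean(pix_sd(rec_acc))

  list(sd_shear_rad = sd_shear,
       sd_recon_rad = sd_rec,
       sd_ratio = sd_rec / sd_shear,
       n_frames = n_frames,
       theory_ratio = dual_noise_theory_ratio(beta_a, beta_b, config))
}

# white-noise prediction: sqrt(mean over the demodulation window of
# 1/(4*(sin^2+sin^2+sin'^2+sin'^2))), DC excluded
#' @keywords internal
dual_noise_theory_ratio <- function(beta_a, beta_b, config,
                                    window_frac = 0.4) {
  n <- config$n_pixels
  k <- centered_index(n)
  g <- sin(pi * beta_a * k)^2 + sin(pi * beta_b * k)^2
  gg <- outer(g, g, "+")
  fc_bins <- carrier_frequency(config) * config$beam_size_mm
  r <- min(window_frac * fc_bins, floor(n / 2))
  inside <- sqrt(outer(k^2, k^2, "+")) <= r
  inside[floor(n / 2) + 1, floor(n / 2) + 1] <- FALSE  # DC carries no noise
  sqrt(mean(1 / (4 * gg[inside])))
}

#' Reconstruction error versus inter-arm translational offset
#'
#' Renders arm B with a sub-pixel translation of the recorded frame (the
#' model of camera misalignment or vibration), runs the dual-shear pipeline
#' at each offset, and reports the maximum and RMS reconstruction error
#' relative to the phantom's peak-to-valley. Both errors grow linearly with
#' the offset over the sub-pixel range.
#'
#' @param offsets_px numeric vector of x-offsets in sensor pixels (default
#'   `seq(0, 1, by = 0.2)`).
#' @param phantom [phase_map()] under test; default: a 136-nm etched circular
#'   target spanning 30% of the field, with its edge softened by the imaging
#'   point-spread function so the target is band-limited within the retrieval
#'   window (the magnification projecting the physical 12-um target onto the
#'   sensor is a free parameter of the study).
#' @param config an [acq_config()]; the default study uses a reduced sensor
#'   and retrieval grid for speed.
#' @param beta_a,beta_b shear ratios of the two arms.
#' @param interior_frac fraction of the field (centered) over which the error
#'   metrics are evaluated (default 0.8). The excluded rim is where the beam
#'   aperture ends and the demodulation envelope vanishes, so it carries no
#'   usable measurement in a real instrument.
#' @return Data frame with `offset_px`, `max_err_rel`, `rms_err_rel`
#'   (fractions of the phantom peak-to-valley).
#' @export
offset_error_study <- function(offsets_px = seq(0, 1, by = 0.2),
                               phantom = NULL,
                               config = acq_config(grating_pitch_um = 60,
                                                   sensor_pixels = 1024,
                                                   n_pixels = 128,
                                                   bit_depth = 16),
                               beta_a = 0.0188, beta_b = 0.0157,
                               interior_frac = 0.8) {
  phantom <- phantom %||%
    make_disc_phantom(0.3 * config$beam_size_mm * 1000, 136, n_pixels = 256,
                      extent_um = config$beam_size_mm * 1000,
                      edge_sigma_um = 2 * config$beam_size_mm * 1000 /
                        config$n_pixels)
  if (!isTRUE(all.equal(phantom$extent_mm, config$beam_size_mm))) {
    stop("phantom extent must match the beam size")
  }
  l_a <- distance_for_shear(beta_a * config$beam_size_mm, config)
  l_b <- distance_for_shear(beta_b * config$beam_size_mm, config)
  frame_a <- render_interferogram(phantom, config, l_a)
  truth <- remove_piston_tilt(resample_phase_map(phantom, config$n_pixels))$values
  p2v <- diff(range(truth))
  recon_at <- function(off) {
    frame_b <- render_interferogram(phantom, config, l_b,
                                    offset_px = c(off, 0))
    remove_piston_tilt(suppressWarnings(run_pipeline(frame_a, frame_b))$phase)$values
  }
  # the aligned reconstruction is the systematic baseline: errors reported are
  # those caused by the offset alone, over the usable beam interior
  n <- config$n_pixels
  half <- floor(interior_frac * n / 2)
  keep <- (floor(n / 2) + 1 - half):(floor(n / 2) + 1 + half)
  ref <- recon_at(0)
  res <- lapply(offsets_px, function(off) {
    err <- (recon_at(off) - ref)[keep, keep]
    err <- err - mean(err)
    c(max_err_rel = max(abs(err)) / p2v, rms_err_rel = rms(err) / p2v)
  })
  out <- data.frame(offset_px = offsets_px, do.call(rbind, res))
  rownames(out) <- NULL
  out
}
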