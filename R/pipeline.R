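# End-to-end retrieval: demodulate both frames, unwrap the four shearing
# phases with DLPU, fuse the spectra of the two shears, optionally subtract a
# stored background. A QC report carries the carrier locations, the process
# step inventory, per-arm shear-consistency residuals and stage timings.

#' Run the full dual-shear phase retrieval pipeline
#'
#' @param frame_a,frame_b interferograms of the two arms (different shears;
#'   equal shears fall back to single-shear reconstruction with a warning).
#' @param config an [acq_config()]; defaults to the config of `frame_a`.
#' @param background optional background [phase_map()] (OPD nm) to subtract.
#' @param weights,eps passed to [reconstruct_dual()].
#' @param window_frac,taper passed to [extract_shearing_phases()].
#' @return A `qwlsi_result`: list with `phase` (a [phase_map()], OPD nm) and
#'   `qc` (carriers, step counts, residuals, suppressed bins, timings).
#' @export
run_pipeline <- function(frame_a, frame_b, config = NULL, background = NULL,
                         weights = c(1, 1), eps = 1e-6,
                         window_frac = 0.4, taper = TRUE) {
  stopifnot(inherits(frame_a, "interferogram"), inherits(frame_b, "interferogram"))
  config <- config %||% frame_a$config
  single <- isTRUE(all.equal(frame_a$shear_mm, frame_b$shear_mm))
  if (single) {
    warning("frames share one shear; falling back to single-shear reconstruction")
  }
  timings <- c()
  tic <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- force(expr)
    timings[name] <<- unname(proc.time()[3] - t0)
    out
  }

  carriers_a <- locate_carriers(frame_a)
  carriers_b <- locate_carriers(frame_b)
  # demodulation: one interferogram FFT each, one crop+IFFT per sideband
  pair_a <- tic("demodulate_a", extract_shearing_phases(
    frame_a, carriers_a, window_frac = window_frac, taper = taper))
  pair_b <- tic("demodulate_b", extract_shearing_phases(
    frame_b, carriers_b, window_frac = window_frac, taper = taper))

  upair_a <- tic("unwrap_a", unwrap_pair(pair_a))
  upair_b <- tic("unwrap_b", unwrap_pair(pair_b))

  phase <- tic("reconstruct", if (single) {
    reconstruct_single(upair_a, config, eps = eps)
  } else {
    suppressWarnings(
      reconstruct_dual(upair_a, upair_b, config, weights = weights, eps = eps))
  })
  if (!is.null(background)) phase <- subtract_background(phase, background)

  steps <- if (single) {
    c(fft_interferogram = 2L, crop_ifft = 2L, unwrap = 2L,
      fft_shearing_wavefront = 2L, least_squares_fit = 1L,
      ifft_wavefront_spectrum = 1L)
  } else {
    c(fft_interferogram = 2L, crop_ifft = 4L, unwrap = 4L,
      fft_shearing_wavefront = 4L, least_squares_fit = 1L,
      ifft_wavefront_spectrum = 1L)
  }

  qc <- list(
    carriers = list(a = carriers_a, b = carriers_b),
    shear_mm = c(a = frame_a$shear_mm, b = frame_b$shear_mm),
    steps = steps,
    suppressed_bins = attr(phase, "suppressed_bins"),
    residual_rms_nm = c(a = shear_residual(phase, upair_a, config),
                        b = if (single) NA_real_ else
                          shear_residual(phase, upair_b, config)),
    single_shear_fallback = single,
    timings_s = timings
  )
  structure(list(phase = phase, qc = qc), class = "qwlsi_result")
}

# RMS (nm) of: shearing wavefront predicted from the reconstruction vs the
# measured (unwrapped, detilted) shearing wavefront.
#' @keywords internal
shear_residual <- function(phase, upair, config) {
  n <- phase$n_pixels
  fr <- freq_mats(n, phase$extent_mm)
  h <- shear_transfer(fr$u, fr$v, upair$shear_mm)
  f <- fft2(phase$values)
  pred_x <- Re(ifft2(h$hx * f))
  pred_y <- Re(ifft2(h$hy * f))
  scale <- config$wavelength_nm / (2 * pi)
  dx <- detilt_plane(pred_x - upair$phi_x * scale)$detilted
  dy <- detilt_plane(pred_y - upair$phi_y * scale)$detilted
  rms(c(dx, dy))
}

#' @export
print.qwlsi_result <- function(x, ...) {
  cat("<qwlsi_result>\n")
  print(x$phase)
  cat(sprintf("  shears: %.4g / %.4g mm%s\n", x$qc$shear_mm["a"],
              x$qc$shear_mm["b"],
              if (x$qc$single_shear_fallback) " (single-shear fallback)" else ""))
  cat(sprintf("  suppressed non-DC bins: %d\n", x$qc$suppressed_bins))
  cat(sprintf("  shear-consistency residual RMS: %.3g / %.3g nm\n",
              x$qc$residual_rms_nm["a"], x$qc$residual_rms_nm["b"]))
  cat("  steps:", paste(names(x$qc$steps), x$qc$steps, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param result a `qwlsi_result` from [run_pipeline()].
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
qc_report_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "qwlsi_result"))
  qc <- result$qc
  qc$carriers <- lapply(qc$carriers, function(cc) lapply(cc, as.numeric))
  qc$steps <- as.list(qc$steps)
  qc$residual_rms_nm <- as.list(qc$residual_rms_nm)
  qc$timings_s <- as.list(qc$timings_s)
  js <- jsonlite::toJSON(qc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
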