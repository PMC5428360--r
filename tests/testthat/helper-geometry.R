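# Reduced acquisition geometry for fast end-to-end tests: coarser grating
# (60 um) keeps the carrier at ~333 of 1024 sensor bins, so a 128-px retrieval
# crop fits with margin. The physics is identical to the full-scale
# 30 um / 2048 px / 501 px configuration.

small_cfg <- function(bit_depth = 16L, n_pixels = 128L) {
  acq_config(grating_pitch_um = 60, sensor_pixels = 1024L,
             n_pixels = n_pixels, bit_depth = bit_depth)
}

# render both arms of a dual-shear acquisition at shear ratios beta
render_pair <- function(phantom, cfg, beta = c(0.0188, 0.0157), ...) {
  lapply(beta, function(b) {
    render_interferogram(phantom, cfg,
                         distance_for_shear(b * cfg$beam_size_mm, cfg), ...)
  })
}

rms_of <- function(x) sqrt(mean(x^2))

detrend <- function(m) qwlsi:::detilt_plane(m)$detilted
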