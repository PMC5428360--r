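# Fourier sideband demodulation: carrier search, closed-form shearing phases,
# achromaticity, energy containment.

test_that("carriers are located within one bin of the configured geometry", {
  cfg <- small_cfg()
  ph <- make_cell_phantom(3, c(0, 150), seed = 4, n_pixels = 128)
  pair <- render_pair(ph, cfg)
  fc_bins <- carrier_frequency(cfg) * cfg$beam_size_mm
  for (f in pair) {
    cc <- locate_carriers(f)
    expect_lte(abs(cc$x["u"] - fc_bins), 1)
    expect_lte(abs(cc$x["v"]), 1)
    expect_lte(abs(cc$y["v"] - fc_bins), 1)
    expect_lte(abs(cc$y["u"]), 1)
  }
  # carrier radius is set by the grating pitch, not by the arm distance
  r <- vapply(pair, function(f) {
    cc <- locate_carriers(f); sqrt(sum(cc$x^2))
  }, numeric(1))
  expect_equal(r[1] / r[2], 1, tolerance = 1e-6)
})

test_that("a pure DC image raises a demodulation failure", {
  cfg <- small_cfg(bit_depth = 8L)
  flat <- qwlsi:::new_interferogram(matrix(100, 256, 256), cfg, 0.1)
  expect_error(locate_carriers(flat), "no sideband peak")
})

test_that("zero phantom demodulates to constant shearing phases", {
  cfg <- small_cfg()
  ph <- phase_map(matrix(0, 128, 128), cfg$beam_size_mm, "opd_nm")
  pr <- extract_shearing_phases(render_pair(ph, cfg)[[1]])
  expect_lt(sd(pr$phi_x), 0.05)
  expect_lt(sd(pr$phi_y), 0.05)
  expect_true(pr$wrapped)
  expect_true(all(pr$phi_x > -pi & pr$phi_x <= pi))
})

test_that("sinusoid shearing-phase amplitude matches the sine transfer", {
  cfg <- small_cfg()
  n_s <- 1024; period_px <- 128; amp <- 0.4
  ph <- make_sinusoid_phantom(period_px, amp, n_s, cfg$beam_size_mm)
  beta <- 0.0188
  f <- render_interferogram(ph, cfg,
                            distance_for_shear(beta * cfg$beam_size_mm, cfg))
  pr <- extract_shearing_phases(f)
  # projection onto the known spatial frequency (8 cycles across the field)
  n <- pr$n_pixels
  cyc <- n_s / period_px
  carrier <- exp(-2i * pi * cyc * (0:(n - 1)) / n)
  proj <- matrix(carrier, n, n, byrow = TRUE)
  measured <- 2 * Mod(mean(detrend(pr$phi_x) * proj))
  theory <- 2 * amp * sin(pi * beta * n_s / period_px)
  expect_equal(measured, theory, tolerance = 0.02)
  # y shearing phase carries no signal for an x-only phantom
  expect_lt(sd(pr$phi_y), 0.05 * theory / 0.4)
})

test_that("linear ramp gives constant phi_x and near-zero phi_y", {
  cfg <- small_cfg()
  n_s <- 1024
  ramp <- phase_map(matrix(0.002 * (0:(n_s - 1)), n_s, n_s, byrow = TRUE),
                    cfg$beam_size_mm, "phase_rad")
  pr <- extract_shearing_phases(render_pair(ramp, cfg)[[1]])
  keep <- 33:96
  expect_lt(sd(pr$phi_x[keep, keep]), 0.02)
  expect_lt(sd(pr$phi_y[keep, keep]), 0.02)
})

test_that("shearing phases are achromatic for an OPD phantom", {
  ph <- make_cell_phantom(4, c(0, 200), seed = 11, n_pixels = 128)
  prs <- lapply(c(614, 632), function(lam) {
    cfg <- acq_config(wavelength_nm = lam, grating_pitch_um = 60,
                      sensor_pixels = 1024L, n_pixels = 128L, bit_depth = 16L)
    f <- render_interferogram(ph, cfg, 3.5)  # same geometry in both arms
    extract_shearing_phases(f)
  })
  d <- detrend(prs[[1]]$phi_x) - detrend(prs[[2]]$phi_x)
  expect_lt(rms_of(d) / rms_of(detrend(prs[[1]]$phi_x)), 0.005)
})

test_that("sideband window contains the signal energy", {
  cfg <- small_cfg()
  ph <- make_cell_phantom(3, c(0, 150), seed = 4, n_pixels = 128)
  f <- render_pair(ph, cfg)[[1]]
  spec <- qwlsi:::fftshift2(qwlsi:::fft2(f$intensity))
  cc <- locate_carriers(f)
  ctr <- floor(1024 / 2) + 1
  h <- 64
  block <- spec[(ctr + cc$x["v"] - h):(ctr + cc$x["v"] + h - 1),
                (ctr + cc$x["u"] - h):(ctr + cc$x["u"] + h - 1)]
  kb <- qwlsi:::centered_index(128)
  rb <- sqrt(outer(kb^2, kb^2, "+"))
  r <- min(0.4 * sqrt(sum(cc$x^2)), 64)
  expect_gte(sum(Mod(block[rb <= r])^2) / sum(Mod(block)^2), 0.95)
})

test_that("window misuse raises errors", {
  cfg <- small_cfg()
  ph <- phase_map(matrix(0, 128, 128), cfg$beam_size_mm, "opd_nm")
  f <- render_pair(ph, cfg)[[1]]
  # overlapping windows: a wide crop block lets the window radius reach
  # halfway between the two carriers
  expect_error(extract_shearing_phases(f, window_frac = 0.9, out_pixels = 480),
               "overlap")
  # window clipped by the spectrum edge
  expect_error(extract_shearing_phases(f, out_pixels = 1001), "clipped")
})
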