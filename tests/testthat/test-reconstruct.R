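# Spectral wavefront recovery: transfer factors, single- and dual-shear
# fusion, spectral leaking, depth conversion, background subtraction.

# exact shearing pair of a known wavefront, via integer-pixel circular shifts
exact_pair <- function(w_nm, extent_mm, shear_px, wavelength_nm = 623) {
  n <- nrow(w_nm)
  stopifnot(shear_px %% 2 == 0)
  h <- shear_px / 2
  # samp(dx, dy)[x, y] = W(x + dx, y + dy) by circular indexing
  samp <- function(m, dx, dy) {
    m[qwlsi:::shift_idx(n, dy), qwlsi:::shift_idx(n, dx)]
  }
  wx <- samp(w_nm, -h, 0) - samp(w_nm, +h, 0)   # W(x-s/2) - W(x+s/2)
  wy <- samp(w_nm, 0, -h) - samp(w_nm, 0, +h)
  scale <- 2 * pi / wavelength_nm
  shearing_pair(wx * scale, wy * scale, shear_px / n * extent_mm, extent_mm,
                wavelength_nm, wrapped = FALSE)
}

test_that("shear transfer factors match the sine closed form", {
  expect_equal(shear_transfer(0, 0.3, 0.1)$hx, -2i * sin(0))
  s <- 0.13
  expect_equal(shear_transfer(1 / (2 * s), 0, s)$hx, -2i)

  # applying the factors reproduces the spatial shift difference
  n <- 64; extent <- 1
  w <- random_smooth_phase(n, 100, seed = 21)
  shear_px <- 8
  s <- shear_px / n * extent
  fr <- qwlsi:::freq_mats(n, extent)
  h <- shear_transfer(fr$u, fr$v, s)
  wx_spec <- Re(qwlsi:::ifft2(h$hx * qwlsi:::fft2(w)))
  pr <- exact_pair(w, extent, shear_px, 623)
  expect_lt(rms_of(wx_spec - pr$phi_x * 623 / (2 * pi)), 1e-9)
})

test_that("single-shear reconstruction inverts the forward model", {
  n <- 127; extent <- 7.066  # odd grid: no Nyquist bin on the shear lattice
  cfg <- acq_config(n_pixels = n)
  w <- random_smooth_phase(n, 150, seed = 31)
  pr <- exact_pair(w, extent, 6)   # shear off the zero lattice
  rec <- reconstruct_single(pr, cfg)
  expect_lt(rms_of(rec$values - (w - mean(w))) / diff(range(w)), 0.01)
  expect_equal(attr(rec, "suppressed_bins"), 0L)

  z <- shearing_pair(matrix(0, n, n), matrix(0, n, n), 0.1, extent,
                     wrapped = FALSE)
  expect_equal(max(abs(reconstruct_single(z, cfg)$values)), 0)

  expect_error(reconstruct_single(
    shearing_pair(matrix(0, 16, 16), matrix(0, 16, 16), 0.1, 1), cfg),
    "unwrapped")
})

test_that("reconstruction is linear in the shearing pair", {
  n <- 64; cfg <- acq_config(n_pixels = n)
  w <- random_smooth_phase(n, 80, seed = 41)
  pr <- exact_pair(w, 7.066, 4)
  pr3 <- shearing_pair(3 * pr$phi_x, 3 * pr$phi_y, pr$shear_mm, pr$extent_mm,
                       pr$wavelength_nm, wrapped = FALSE)
  expect_equal(reconstruct_single(pr3, cfg)$values,
               3 * reconstruct_single(pr, cfg)$values, tolerance = 1e-10)
})

test_that("dual-shear fusion collapses to single-shear for equal shears", {
  n <- 64; cfg <- acq_config(n_pixels = n)
  w <- random_smooth_phase(n, 80, seed = 51)
  pr <- exact_pair(w, 7.066, 4)
  expect_warning(rec2 <- reconstruct_dual(pr, pr, cfg), "equal shears")
  rec1 <- reconstruct_single(pr, cfg)
  expect_equal(rec2$values, rec1$values, tolerance = 1e-12)
})

test_that("dual-shear fusion recovers the wavefront and is self-consistent", {
  n <- 127; extent <- 7.066; cfg <- acq_config(n_pixels = n)
  w <- random_smooth_phase(n, 150, seed = 61)
  pa <- exact_pair(w, extent, 6)
  pb <- exact_pair(w, extent, 10)
  rec <- reconstruct_dual(pa, pb, cfg)
  expect_lt(rms_of(rec$values - (w - mean(w))) / diff(range(w)), 0.01)

  # residual shear consistency: re-sheared output matches the inputs
  fr <- qwlsi:::freq_mats(n, extent)
  h <- shear_transfer(fr$u, fr$v, pa$shear_mm)
  wx_pred <- Re(qwlsi:::ifft2(h$hx * qwlsi:::fft2(rec$values)))
  expect_lt(rms_of(wx_pred - pa$phi_x * 623 / (2 * pi)) / diff(range(w)),
            1e-3)
})

test_that("spectral leaking: lattice noise is amplified by one shear only", {
  n <- 101; extent <- 7.066
  cfg <- acq_config(n_pixels = n)
  beta_a <- 0.02            # zero lattice on-grid at every 50th bin... k*0.02
  w <- matrix(0, n, n)
  pa <- exact_pair(w, extent, 2)  # shear 2 px -> beta = 2/101
  # inject noise near the arm-A lattice: bins adjacent to u = 1/s
  spike <- matrix(0, n, n)
  spike[1, 51] <- 40 + 0i   # fft-order u bin k = 50, adjacent to the lattice
  noise_x <- Re(qwlsi:::ifft2(spike)) * n^2
  scale <- 2 * pi / 623
  mk <- function(base, s_px) shearing_pair(
    (base) * scale, matrix(0, n, n), s_px / n * extent, extent, 623,
    wrapped = FALSE)
  single <- reconstruct_single(mk(noise_x, 2), cfg)
  dual <- suppressWarnings(
    reconstruct_dual(mk(noise_x, 2), mk(matrix(0, n, n), 3), cfg))
  # the same injected noise blows up through the near-zero single-shear
  # denominator but is tamed by the second shear
  expect_gt(rms_of(single$values) / rms_of(dual$values), 5)
})

test_that("opd_to_depth applies z = OPD/(n-1)", {
  pm <- make_disc_phantom(12, 136, 1.457, 64, 36)
  depth <- opd_to_depth(pm, 1.457)
  expect_equal(max(abs(depth$values)), 136, tolerance = 1e-9)
  expect_equal(depth$unit, "depth_nm")
  expect_equal(opd_to_depth(phase_map(matrix(0, 8, 8), 1, "opd_nm"),
                            1.5)$values, matrix(0, 8, 8))
  expect_error(opd_to_depth(pm, 1), "exceed")
})

test_that("etch depth survives the full pipeline within 2%", {
  cfg <- acq_config(grating_pitch_um = 60, sensor_pixels = 1024L,
                    n_pixels = 128L, bit_depth = 16L)
  disc <- make_disc_phantom(0.3 * 7066, 136, refractive_index = 1.457,
                            n_pixels = 256, extent_um = 7066)
  l <- vapply(c(0.0188, 0.0157) * cfg$beam_size_mm,
              function(s) distance_for_shear(s, cfg), numeric(1))
  res <- run_pipeline(render_interferogram(disc, cfg, l[1]),
                      render_interferogram(disc, cfg, l[2]))
  depth <- opd_to_depth(res$phase, 1.457)
  r <- sqrt(outer((-63.5:63.5)^2, (-63.5:63.5)^2, "+")) / 128 * 7066
  est <- abs(median(depth$values[r < 0.7 * 0.15 * 7066]) -
             median(depth$values[r > 1.5 * 0.15 * 7066]))
  expect_equal(est, 136, tolerance = 0.02)
})

test_that("background subtraction removes stored systematics", {
  a <- phase_map(centered_gaussian(32, 50) + 7, 1, "opd_nm")
  expect_equal(max(abs(subtract_background(a, a)$values)), 0)

  aberr <- phase_map(random_smooth_phase(32, 30, seed = 71), 1, "opd_nm")
  meas <- phase_map(a$values + aberr$values, 1, "opd_nm")
  rec <- subtract_background(meas, aberr)
  expect_equal(rec$values, a$values - mean(a$values), tolerance = 1e-10)

  # subtracting a zero background is the identity up to piston
  z <- phase_map(matrix(0, 32, 32), 1, "opd_nm")
  expect_equal(subtract_background(a, z)$values, a$values - mean(a$values))

  expect_error(subtract_background(a, phase_map(matrix(0, 16, 16), 1, "opd_nm")),
               "grid")
})
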