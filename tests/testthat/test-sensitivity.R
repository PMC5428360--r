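# Spectral sensitivity engine: closed forms, zero lattices, SD map structure,
# shear-pair optimization, centroid offset estimation.

test_that("single-shear sensitivity evaluates Eq-form closed values", {
  # both sines at +/-1: sigma = 2*sqrt(2); beta*k = 0.5 at k = 200
  m <- sigma_single(0.0025, 7.066, 501)
  ctr <- 251
  expect_equal(m$values[ctr + 200, ctr + 200], 2 * sqrt(2))
  expect_equal(m$values[ctr, ctr], 0)           # DC
  expect_true(all(m$values >= 0 & m$values <= 2 * sqrt(2) + 1e-12))

  # zero lattice u = m/s: beta = 0.02 vanishes at every 50th bin
  m2 <- sigma_single(0.02, 7.066, 501)
  lat <- ctr + seq(-250, 250, by = 50)
  expect_true(all(m2$values[lat, lat] < 1e-9))
  expect_gt(min(m2$values[ctr + 25, ]), 0.5)    # off-lattice rows are alive

  # symmetry: even in u and v, u <-> v exchange
  expect_equal(m2$values, m2$values[, 501:1])
  expect_equal(m2$values, m2$values[501:1, ])
  expect_equal(m2$values, t(m2$values))
})

test_that("uncertainty ratio is the reciprocal sensitivity", {
  s <- 0.133
  # odd half-lattice: 1/(2*sqrt(2))
  expect_equal(uncertainty_ratio(1 / (2 * s), 3 / (2 * s), s), 1 / (2 * sqrt(2)))
  # sigma = 2 when one sine is 1 and the other 0
  expect_equal(uncertainty_ratio(1 / (2 * s), 1 / s, s), 0.5)
  set.seed(4)
  for (i in 1:5) {
    u <- runif(1, 0.1, 5); v <- runif(1, 0.1, 5)
    sig <- 2 * sqrt(sin(pi * s * u)^2 + sin(pi * s * v)^2)
    expect_equal(uncertainty_ratio(u, v, s) * sig, 1, tolerance = 1e-12)
  }
  expect_warning(r <- uncertainty_ratio(1 / s, 2 / s, s), "unbounded")
  expect_true(is.infinite(r))
})

test_that("dual sensitivity: algebraic collapse, zero count, maximum", {
  # equal shears reduce exactly to the single-shear map
  expect_equal(sigma_dual(0.02, 0.02, 7.066, 101)$values,
               sigma_single(0.02, 7.066, 101)$values, tolerance = 1e-12)

  # the optimal pair leaves a single zero: DC
  m <- sigma_dual(0.0188, 0.0157, 7.066, 501)
  expect_identical(count_zero_bins(m), 1L)
  # while any equal-shear pair zeroes a whole lattice
  expect_gt(count_zero_bins(sigma_dual(0.02, 0.02, 7.066, 501)), 1L)

  # mean sensitivity of the optimal pair is around 2
  expect_gte(mean(m$values), 1.8)
  expect_lte(mean(m$values), 2.1)

  # maximum sqrt(2)*2 attained only when all four sines are simultaneously
  # +/-1 (grid-search oracle over a commensurate pair)
  mc <- sigma_dual(0.0025, 0.0075, 7.066, 501)
  expect_equal(max(mc$values), 2 * sqrt(2), tolerance = 1e-12)
  expect_lt(max(m$values), 2 * sqrt(2))  # incommensurate pair stays below
})

test_that("SD map is symmetric with a diagonal ridge", {
  m <- sd_map(0.0157, 0.0188, n_steps = 11, n_pixels = 501)
  expect_lt(max(abs(m - t(m))), 1e-12)

  # diagonal entries are local maxima against off-diagonal neighbours
  for (i in c(3, 6, 9)) {
    expect_gt(m[i, i], m[i, i - 1])
    expect_gt(m[i, i], m[i, i + 1])
  }
  # the printed optimal pair beats its equal-shear diagonal partner
  expect_lt(m["0.0188", "0.0157"], m["0.0188", "0.0188"])
})

test_that("shear-pair optimization picks an off-diagonal valley", {
  best <- optimize_shear_pair(0.0157, 0.0188, n_steps = 11, n_pixels = 301)
  expect_true(best["beta_a"] < best["beta_b"])   # strictly off-diagonal
  sdm <- sd_map(0.0157, 0.0188, n_steps = 11, n_pixels = 301)
  expect_equal(unname(attr(best, "sd")), min(sdm[abs(outer(attr(sdm, "beta"),
    attr(sdm, "beta"), "-")) > 1e-9]))

  # order invariance of the range endpoints
  best2 <- optimize_shear_pair(0.0188, 0.0157, n_steps = 11, n_pixels = 301)
  expect_equal(best, best2)

  expect_error(optimize_shear_pair(0.0157, 0.0188, n_steps = 11,
                                   n_pixels = 101, min_separation = 0.1),
               "min_separation")
})

test_that("centroid offset estimation recovers known shifts", {
  disc <- make_disc_phantom(12, 136, n_pixels = 256, extent_um = 36)
  expect_equal(estimate_offset(disc, disc), c(dx = 0, dy = 0))

  shifted <- phase_map(qwlsi:::fourier_shift(disc$values, c(1, 0)),
                       disc$extent_mm, "opd_nm")
  off <- estimate_offset(disc, shifted)
  expect_lt(abs(off["dx"] - 1), 0.05)
  expect_lt(abs(off["dy"]), 0.05)

  set.seed(8)
  noise <- phase_map(matrix(rnorm(256^2), 256), disc$extent_mm, "opd_nm")
  expect_error(estimate_offset(noise, noise), "compact")
})
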