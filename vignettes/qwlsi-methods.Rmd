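---
title: "Dual-shear quadriwave lateral shearing interferometry: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-shear quadriwave lateral shearing interferometry: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(qwlsi)
```

## The measurement model

A quadriwave lateral shearing interferometer (QWLSI) is a self-referenced
phase microscope: a diffractive element with exactly four first orders splits
the wavefront under test $W(x, y)$ into four replicas, tilted by
$\pm\sqrt{2}/d$ cycles per unit length along the two sensor axes ($d$ is the
grating pitch) and laterally displaced by $\pm s/2$ along the same axis. The
lateral shear between an interfering pair is set by the grating-to-sensor
distance $l$:

$$s = 2\sqrt{2}\,l\lambda/d .$$

Because the shear varies continuously with $l$, the sensitivity of the
instrument is tunable. The interference of the $+1/-1$ pair along $x$ puts
the *shearing wavefront*

$$W_x(x,y) = W(x - s/2,\, y) - W(x + s/2,\, y)$$

on a fringe carrier at $2\sqrt{2}/d$; likewise $W_y$ along $y$. In the
Fourier domain the shearing operation is multiplicative:

$$F_x(u,v) = -2i\,\sin(\pi s u)\, F(u,v), \qquad
  F_y(u,v) = -2i\,\sin(\pi s v)\, F(u,v),$$

so a sinusoidal component of period $D$ is amplified by up to a factor of 2
when $s = D/2$, and annihilated when $s$ is a multiple of $D$. The phases of
the shearing wavefronts, $\phi_{x,y} = (2\pi/\lambda) W_{x,y}$, reduce in the
small-shear limit to $(4\pi\sqrt{2}\,l/d)\,\partial W/\partial x$ (and $y$):
the wavelength cancels, which is why the measurement is achromatic for an
optical-path-difference (OPD) object and why a broadband LED source can be
modelled at its dominant wavelength (623 nm here). `render_interferogram()`
implements exactly this scalar, monochromatic four-wave model, followed by
optional sub-pixel frame translation (camera misalignment/vibration), Poisson
shot noise, and quantization.

## Spectral sensitivity and the dual-shear design

Relative to an interferometer with an external reference and the same photon
budget, the single-shear QWLSI has spectral sensitivity

$$\sigma(u,v) = 2\sqrt{\sin^2(\pi s u) + \sin^2(\pi s v)},$$

with uncertainty $\Delta = \Delta_0/\sigma$: as low as $1/(2\sqrt2)$ of the
reference at the odd half-lattice frequencies, but unbounded on the lattice
$u = m/s,\ v = n/s$, where noise is amplified by the vanishing denominator of
the reconstruction — the *spectral leaking* artifact. Splitting the beam over
two QWLSIs with shears $s \ne s'$ costs $\sqrt 2$ in shot noise but removes
every shared zero except DC:

$$\sigma'(u,v) = \sqrt{2}\cdot\sqrt{\sin^2(\pi s u)+\sin^2(\pi s v)
  +\sin^2(\pi s' u)+\sin^2(\pi s' v)} .$$

`sigma_single()`, `sigma_dual()` and `uncertainty_ratio()` evaluate these on
the centered discrete grid $u_k = k/L$ (field size $L = 7.066$ mm, $501^2$
bins by default, so $s\,u$ reduces to $\beta k$ with shear ratio
$\beta = s/L$). A flat $\sigma'$ is the design goal: `sd_map()` scans the
population SD of $\sigma'$ over pairs $(\beta, \beta')$ — a ridge on the
diagonal (equal shears) flanked by two valleys — and `optimize_shear_pair()`
picks the off-diagonal minimum. The pair $(1.88\%, 1.57\%)$ used throughout
sits in such a valley and leaves exactly one zero bin (DC) on the $501^2$
grid, with mean $\sigma' \approx 1.98$.

A note on the maximum of $\sigma'$: all four sines reach $\pm 1$
simultaneously only for commensurate pairs, giving
$\sqrt2\cdot\sqrt4 = 2\sqrt2$, the same ceiling as the single-shear map.

## Phase retrieval

`run_pipeline()` chains the stages; each is exported.

**Demodulation** (`locate_carriers()`, `extract_shearing_phases()`). The
sideband of each shearing direction is found as the spectral magnitude peak
inside an angular cone around the corresponding sensor axis — a global
search would instead find the diagonal cross terms between the $x$ and $y$
order pairs, which have comparable magnitude. A square block of the centered
spectrum, one retrieval pixel per sensor-spectrum bin, is cropped around the
carrier (translating it to DC), windowed (circular, raised-cosine taper over
the outer 20% by default, radius 40% of the carrier separation), and
inverse-transformed; its argument is the wrapped shearing phase. The crop
width *is* the output resolution — a 501-px crop of a 2048-px spectrum yields
the 501×501 retrieval grid without zero padding. Because
$2\sqrt2\,L/d = 666.19$ is not an integer, the carrier falls between bins;
the known fractional part is removed from the demodulated field
(`subbin_correction = TRUE`), the software analogue of carrier calibration —
without it the residual ramp in each shearing phase integrates into a large
spurious quadratic.

**Differential leveling phase unwrapping** (`unwrap_dlpu()`). A
path-independent unwrapper built from element-wise operations and FFTs:
periodic forward differences of the wrapped phase; *leveling* (re-wrapping
each differential into $(-\pi,\pi]$, which restores the true differential
wherever the true gradient is below $\pi$/pixel); least-squares Fourier
integration of the leveled differentials into a *reference phase* (the
one-pixel-shear special case of the spectral retrieval, DC fixed to zero);
then a per-pixel correction of the wrapped input by
$2\pi\,\mathrm{round}\!\big((\text{reference}-\text{wrapped})/2\pi\big)$
after removing the least-squares tilt from both. The output is congruent to
the input modulo $2\pi$ at every pixel by construction; recovery is exact (up
to a global $2\pi$ multiple) whenever the true gradient stays below
$\pi$/pixel, and best-effort on residue-carrying inputs — the algorithm has
no residue handling, by design. Ties in the rounding (differences of exactly
$\pi$) round half away from zero, fixed for reproducibility. Periodic
differences keep the DFT integration self-consistent; since the reference
only enters through a rounding, boundary artifacts rarely change the jump
count. The test suite checks it against a sequential quality-guided
unwrapper.

**Spectral fusion** (`reconstruct_single()`, `reconstruct_dual()`). The
wavefront spectrum is the per-frequency least-squares solution of the two
(or four) observations with design coefficients $-2i\sin(\pi s u)$ etc.:

$$\hat F = i\,\frac{\sum_k w_k \sin_k F_k}{2\sum_k w_k \sin_k^2},$$

equal weights by default (exposure weights are exposed). Bins whose
denominator falls below $10^{-6}$ of its maximum are zeroed and counted —
these are the leaking bins; for the optimal dual pair the count is zero.
Piston is unobservable and fixed to zero; tilt is reconstructable and kept.
`opd_to_depth()` converts OPD to etch depth via $z = \mathrm{OPD}/(n-1)$, and
`subtract_background()` removes a stored background acquisition — the
instrument's systematic-error calibration.

## The synthetic-data generator

`make_sinusoid_phantom()`, `make_disc_phantom()` and `make_cell_phantom()`
generate the study objects: the sensitivity sinusoid, the etched circular
target (12 µm diameter, 136 nm depth, fused quartz $n = 1.457$ by default;
etching lowers the OPD, so the disc is negative), and a reproducible
band-limited field of Gaussian/biconcave blobs standing in for cell fields.
The cell phantom applies a super-Gaussian field stop so the field is
effectively periodic for Fourier processing. The disc optionally takes a
Gaussian edge softening (`edge_sigma_um`) emulating the imaging PSF; the
ideal hard edge is the default.

Noise defaults model the photon-starved acquisition the method was
characterized with: 8-bit frames peaking at gray 132, Poisson mean 1000 at
the peak — giving a 4.2-gray SD at the brightest pixel and frame-to-frame
extremes near 27 gray over a 4-megapixel frame, and shearing-phase temporal
SDs of ≈0.03 rad. Every random draw takes an explicit seed and restores the
caller's RNG state.

What the generator does *not* emulate: partial coherence and speckle,
grating fabrication error and parasitic orders, camera read noise and dark
current, mechanical drift within a frame, and optical aberrations beyond a
static background. Passing tests therefore demonstrate the correctness of
the retrieval chain under the stated model, not robustness to every
instrument imperfection.

## Numerical choices and measurement conventions

* Grids are square; pixel (1,1) is top-left, x rightward (columns), y
  downward (rows); frequency grids are centered with a single DC bin (odd
  sizes preferred: 501, 101).
* The retrieval is evaluated at full scale (2048-px sensor, 501-px
  retrieval) for the noise study and round trip; development-scale checks
  use a 60-µm pitch with a 1024-px sensor and 128-px retrieval, which keeps
  the same carrier-to-window proportions.
* Round-trip fidelity is quoted after background calibration. The
  uncalibrated pipeline carries a ≈1% systematic from the taper-truncated
  spectral tails of the non-integer carrier; one background acquisition
  removes it (to ~10⁻⁶ relative), exactly as a real instrument is used.
* The inter-arm offset study (`offset_error_study()`) reports errors over
  the interior 80% of the field. At the field rim the demodulation envelope
  vanishes (beam aperture edge) and conjugate-sideband leakage dominates;
  the interior metrics grow linearly with the injected offset
  (R² > 0.99 for both max and RMS), reaching ≈1% of the target range at one
  camera pixel.
* `sd_map()` includes the DC bin in the SD by default (exclusion is a flag);
  the optimizer breaks ties toward the smaller first ratio.
* Problem sizes in the tests: the shot-noise study uses 50 frames per arm at
  full scale; the unwrapping oracle comparisons run on 64² grids; the
  SD-map structure checks use an 11×11 ratio grid. These sizes give stable
  statistics while keeping the suite quick to run.

## Temporal noise: what "half" means

With the optimal pair the *mean* sensitivity is ≈2, and the per-pixel
temporal SD of the dual-shear reconstruction is about half the temporal SD
of the directly measured shearing phases when the noise is concentrated at
frequencies where $\sigma'\approx 2$. Under strictly white shot noise the
proper aggregation is quadratic,

$$\frac{\mathrm{SD}_{\text{recon}}}{\mathrm{SD}_{\text{shear}}}
 = \sqrt{\Big\langle \tfrac{1}{2\sigma'^2(u,v)} \Big\rangle_{\text{window}}},$$

which evaluates to ≈0.38 for $(1.88\%, 1.57\%)$ — the reciprocal-mean
heuristic $1/\langle\sigma'\rangle \approx 0.5$ is an upper summary of the
same map. `temporal_sd_study()` measures the ratio through the full pipeline
(50 shot-noise frame pairs) and returns both the measurement (≈0.39) and the
white-noise prediction; real acquisitions, whose noise spectra are tilted
toward low frequencies by residual vibration, land nearer the heuristic.

## Known limitations

* No residue handling in the unwrapper (inherited from the algorithm): heavy
  noise can produce local $2\pi$ errors.
* The single-shear regularization threshold ($10^{-6}$, relative) is a
  design choice; the method's authors publish no value.
* Only two shears are fused; no zonal (Southwell-type) or iterative
  reconstruction.
* The forward model is scalar and monochromatic; partial coherence is
  declared negligible via the achromaticity of the shearing phases rather
  than simulated.

## A worked example

```{r example, eval = FALSE}
cfg <- acq_config()                       # 623 nm, 30 um pitch, 7.066 mm field
ph  <- make_cell_phantom(5, c(0, 250), seed = 3, n_pixels = 501)
l   <- sapply(c(0.0188, 0.0157) * cfg$beam_size_mm, distance_for_shear,
              config = cfg)
fa  <- render_interferogram(ph, cfg, l[1], noise = "shot", seed = 1)
fb  <- render_interferogram(ph, cfg, l[2], noise = "shot", seed = 2)
res <- run_pipeline(fa, fb)
plot(res$phase)
```
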