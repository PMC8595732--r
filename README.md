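# fsflim

Simulation and analysis of **full-spectral fluorescence lifetime imaging
(FS-FLIM)** data: photon-count cubes recorded by a confocal scanning
microscope whose emission path is dispersed onto a 512-channel SPAD line
sensor with on-chip time-correlated single photon counting (TCSPC)
histogramming. Every image pixel carries a full emission spectrum
(500–760 nm at ~0.5 nm per channel) that is time-resolved into 32 (or 16
chained) arrival-delay bins, so a single acquisition yields a 4-D cube
(row, col, spectral channel, time bin).

The package is for instrument and analysis developers working with such
hyperspectral TCSPC cubes. It provides:

- a **data model and container** for FS-FLIM cubes (axes with explicit
  half-open edge conventions, 10-bit/20-bit counter bounds, lossless
  versioned binary container, multi-page TIFF export, JSON sidecars);
- a **physics-based simulator** with known ground truth: Gaussian emission
  bands, IRF-convolved single-exponential decays, Poisson shot noise, dark
  counts, wavelength-dependent photon detection efficiency (PDE), and
  counter saturation/chaining;
- the **correction chain**: chained-bin decoding, dark-count subtraction,
  spectral-efficiency flat-fielding;
- **thresholded per-channel lifetime fitting**: least squares on
  `I(t) = A·exp(−t/τ) + B` for every surviving (pixel, channel), with the
  10×-background and absolute-count rejection rules, an 8-channel moving
  spectral mean for low-signal spectral limits, per-wavelength lifetime
  histograms and ROI spectral-lifetime summaries;
- **rendering and mosaicking**: wavelength-faithful spectral false-color
  images, lifetime maps with (optionally inverted) intensity-weighted
  transparency, and translation-grid tile stitching with global intensity
  normalization.

## The model in brief

A detected photon in pixel (y, x), spectral channel k and time bin j is a
Poisson draw with expectation

```
E[N(y,x,k,j)] = Σ_f  w_f(y,x) · β_f · T · g_f(k) · η(k)/η_peak · p_f(j)  +  d·T / n_bins
```

where `w_f` is the fluorophore's per-pixel weight, `β_f` its brightness
(detected photons/µs at peak efficiency), `T` the dwell time, `g_f(k)` its
Gaussian emission band integrated over channel k, `η(k)` the PDE curve,
`p_f(j)` the exponentially-modified-Gaussian decay mass in bin j (lifetime
τ_f convolved with a Gaussian IRF), and `d` the dark-count rate. Counters
clip at `2^10 − 1` (raw) or `2^20 − 1` (chained pairs).

Lifetimes are estimated per (pixel, channel) by least squares on the decay
tail from the peak bin onward. For fixed τ the model is linear in (A, B),
so the fit profiles the residual sum over τ only (variable projection)
and is deterministic, with no iteration-failure modes; entries failing the
threshold rules carry τ = 0.

## Worked example

```r
library(fsflim)

saxis <- spectral_axis(32, 500, 760)     # 8.1 nm channels for a quick demo
taxis <- time_axis(32, 50 / 32)          # 1.5625 ns bins over the 50 ns period

safranin  <- fluorophore("safranin-like",  550, 35, 1.9, 80)
fastgreen <- fluorophore("fastgreen-like", 650, 35, 3.1, 80)
w1 <- matrix(0, 32, 32); w1[, 1:16]  <- 1
w2 <- matrix(0, 32, 32); w2[, 17:32] <- 1
scene  <- phantom_scene(list(safranin, fastgreen), list(w1, w2))
sensor <- sensor_config(dark_count_rate = 100)

cube <- simulate_cube(scene, sensor, saxis, taxis,
                      sim_params(dwell_time = 500, seed = 1, chained = TRUE))
cube
#> <flim_cube> 32 x 32 pixels, 32 spectral channels, 32 time bins (chained)
#>   spectral: 500-760 nm | time: 1.5625 ns bins | dwell: 500 us
#>   total photons: 40955531

corr <- subtract_dark(cube, sensor)
bg   <- expected_background_level(sensor, 500, 32)
ltc  <- fit_cube(corr, bg, threshold_policy(10, 2000, smoothing_mode = "off"))
ltc
#> <lifetime_cube> 32 x 32 pixels x 32 channels; 6656 fits attempted, 6656 valid

left <- roi_mean_spectral_lifetime(ltc, w1 > 0)
subset(left, n_valid > 0)[1:4, ]
#>   channel wavelength_nm mean_tau_ns n_valid
#> 4       4      528.4375    1.918031     512
#> 5       5      536.5625    1.926511     512
#> 6       6      544.6875    1.922803     512
#> 7       7      552.8125    1.923280     512
```

The left region's mean spectral lifetime sits within ~1.5% of the
simulated 1.9 ns; the right region recovers ~3.13 ns against a simulated
3.1 ns. `render_color_image()` / `render_lifetime_image()` turn the same
objects into RGB(A) images and `stitch_tiles()` assembles stage-translated
tiles, e.g. the 2 × 10, 0.5 mm-step layout of a tissue mosaic.

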