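---
title: "FS-FLIM cube simulation and analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FS-FLIM cube simulation and analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsflim)
```

## The measurement this package models

Full-spectral FLIM instruments disperse the de-scanned confocal emission of
each image pixel onto a SPAD line sensor whose channels each build a TCSPC
histogram on chip. One acquisition therefore produces a 4-D photon-count
cube indexed (row, col, spectral channel, time bin). The configuration the
defaults emulate is a 512-channel sensor spanning 500–760 nm (≈0.51 nm per
channel), a 20 MHz pulsed laser (50 ns period, <100 ps pulses), 32 time
bins with 10-bit per-bin counters that can be chained in adjacent pairs
into 16 bins of 20-bit capacity, a peak photon detection efficiency (PDE)
of 17%, and a measurable dark-count rate per channel.

### Axis conventions

Channels and bins are uniform with **half-open intervals**: channel $k$
(1-based, the R convention) covers
$[\lambda_{\min}+(k-1)\Delta\lambda,\ \lambda_{\min}+k\Delta\lambda)$, and
likewise for time bins. Half-open intervals make membership unambiguous at
shared edges; a wavelength exactly on an interior edge belongs to the
redder channel. The instrument's calibration could equally place channel
*centers* at 500/760 nm; nothing in the available description settles this,
so the edge convention here is a package choice, stated once and used
everywhere (`spectral_axis()`, `wavelength_to_channel()`).

The default time axis is 32 bins of 1.5625 ns spanning the full 50 ns
period. The sensor's 50 ps timing resolution and 32 bins cannot both span
the laser period (32 × 50 ps = 1.6 ns), and the true observation window of
the hardware is not recorded here, so the bin width is configurable; every
algorithm reads it from the `time_axis` rather than assuming it.

### The container

Cubes are stored in a single-file versioned binary container: an 8-byte
magic string, a 4-byte header length, a JSON header (schema version,
extents, both axes, chaining flag, dwell time, free-form provenance), then
the counts as little-endian unsigned 32-bit words in array order. One
32-bit word size serves both 10-bit raw and 20-bit chained data, which is
also the word size used in the worst-case data-volume arithmetic
(`cube_storage_bits(256, 256, 512, 16, 32)` = 2^34 bits = 16 Gib per
image). Readers reject unknown schema versions and any header/payload
inconsistency outright instead of guessing. A multi-page 32-bit-float TIFF
export (one page per channel × bin, scaled by counter capacity, exact
after rounding back) and a JSON metadata sidecar serve interoperability.

## The simulator: forward model and what it does not emulate

`expected_count_cube()` is the noise-free forward model; the expectation at
(y, x, k, j) is

$$\sum_f w_f(y,x)\,\beta_f\,T\; g_f(k)\,\frac{\eta(k)}{\eta_{peak}}\; p_f(j)
\;+\; \frac{d_k\,T}{n_{bins}}$$

- **Emission** $g_f(k)$: a Gaussian band (center, FWHM) integrated exactly
  over each channel interval via normal CDF differences. Mass outside the
  sensor range is lost, as on the instrument. Real fluorophore spectra are
  asymmetric; a Gaussian is the standard single-parameter-family stand-in
  and is sufficient for testing spectral machinery.
- **Decay** $p_f(j)$: a single-exponential decay convolved with a Gaussian
  IRF — an exponentially modified Gaussian (EMG) arrival density —
  integrated analytically over each bin and renormalized over the observed
  window. The IRF FWHM defaults to 100 ps, the laser pulse bound, with
  detector jitter folded into the same Gaussian; neither the true IRF shape
  nor the combination rule is available, and a Gaussian is the common
  modeling choice. The pure-exponential ($\sigma = 0$) branch uses survival
  -function differences to avoid catastrophic cancellation in far-tail
  bins. Decay wrap-around across the 50 ns period is neglected: for
  nanosecond lifetimes $e^{-50/\tau}$ is far below any other error term.
- **Detection efficiency** enters as the relative weight
  $\eta(k)/\eta_{peak}$, so fluorophore brightness $\beta_f$ (photons/µs at
  unit weight) is defined at the peak-efficiency channel.
- **Dark counts** $d_k$ are uniform over time bins (uncorrelated with the
  laser) and uniform over channels unless a per-channel rate is given.
- **Noise and saturation**: independent Poisson draws per bin, clipped at
  $2^{10}-1$ (raw) or $2^{20}-1$ (chained). A fixed seed gives a
  bit-identical cube.

Not emulated: optical point-spread blur, SPAD afterpulsing and channel
crosstalk, sub-channel (per-SPAD) nonuniformity, multi-exponential decays,
and sample motion or photobleaching. Tests passing on these phantoms
therefore demonstrate the correctness of the processing chain under the
stated forward model, not robustness to every artifact of real tissue
data.

## Corrections

The chain is **decode → dark → flat-field**, recorded as ordered tags with
re-application refused (a second dark subtraction would silently bias
every decay, so it is an error, not a warning).

- `decode_chained()` merges adjacent bin pairs (2j−1, 2j) by summation —
  the counter-chaining the hardware offers for dynamic range; totals are
  conserved and the merged capacity bound is 20-bit.
- `subtract_dark()` removes the expected dark contribution
  $d_k T / n_{bins}$ per bin and clips negatives at zero. Clipping keeps
  corrected cubes non-negative but makes the post-subtraction mean of
  dark-dominated bins slightly positive; this is inherent to clipping, and
  the threshold rules below are what actually protect the fits from
  dark-dominated decays.
- `flatfield_spectral()` divides each channel by $\eta(k)/\eta_{peak}$.
  Detection efficiency is multiplicative, so its inverse is a division
  (flat-fielding), even though a subtractive reading of "correcting the
  spectral efficiency response" would also be conceivable; channels with
  zero efficiency are masked to `NA` rather than divided.

Dark subtraction and flat-fielding commute only for a flat PDE curve, so
the order is fixed dark-first and asserted by the tag sequence.

## Lifetime estimation

### Thresholding

A (pixel, channel) is fitted only if its time-summed intensity reaches
**both** `background_multiple` × the expected per-channel background (10×
by default; the background reference is the expected dark total
$d_k T$, since scattering has no model here) and an absolute floor
(`absolute_min_counts`, 200 by default — the tissue-imaging rule; the
recovery phantoms use 2000, their stated photon budget). Rejected entries
carry τ = 0 in the lifetime map, so the support of the τ map equals the
mask support whenever every surviving decay admits a valid fit.

### The moving spectral mean

`moving_spectral_mean()` replaces each channel by the mean of a
`smoothing_width`-channel window centered on it (even widths extend one
channel to the red; edge windows truncate). Eight channels of the
512-channel axis span 8 × 0.5078 = 4.06 nm. Three modes:

- `off` — no smoothing;
- `full` — the whole spectrum, as used for tissue cubes;
- `edges_only` (default) — only channels whose image-mean intensity falls
  below `absolute_min_counts`. The motivating practice is smoothing "where
  the signal is reduced at the wavelength limits"; an intensity-based rule
  implements that data-dependently instead of hard-coding an edge margin,
  and is recorded in the policy so provenance is explicit.

### The fitter

Each surviving decay is fitted with $I(t) = A e^{-t/\tau} + B$ by least
squares over the bins **from the peak bin onward** (tail fitting), which
sidesteps explicit IRF deconvolution. For fixed τ the model is linear in
(A, B), so the fit solves (A, B) in closed form — with the boundary cases
A = 0 / B = 0 handled explicitly so both stay non-negative — and minimizes
the profiled residual sum over τ alone: a 40-point log-spaced scan over
(≈0, laser period] brackets the optimum and Brent's method (tolerance
1e-10 ns) refines it. This variable-projection route is deterministic and
has no convergence-failure modes, unlike a generic 3-parameter iterative
minimizer; an exhaustive 3-D grid search over (A, τ, B) serves as the
independent oracle in the test suite and never beats the fitter's
residual.

A fit is **invalid** (τ reported as 0) when fewer than 3 tail bins hold
positive counts, the profiled solution has non-positive amplitude, or the
decay term fails to improve on a constant-background fit; invalidity is a
result, never an exception, so cube-scale fitting degrades gracefully.
Poisson-weighted least squares (weights $1/\max(y,1)$) is available behind
a flag; the default is unweighted, matching plain least-squares practice.
The Pearson statistic $\sum (y-\hat y)^2/\max(\hat y, 1)$ is returned as
the fit-quality number.

**Known limitation**: because the peak bin contains the instrument rise,
tail fitting of IRF-convolved decays keeps a small systematic
underestimate that no photon budget removes — below 3% of τ at the default
geometry (100 ps IRF, 1.5625 ns bins, τ ≈ 2 ns), and far inside the 5%
recovery tolerance used throughout. On IRF-free decays the estimator's
bias is statistically indistinguishable from zero and the spread contracts
with the photon budget, as the test suite checks at 500/5,000/50,000
photons.

### Summaries

`lifetime_histogram()` counts valid pixels at one channel into half-open
ns bins (the per-wavelength lifetime distributions of whole images);
`roi_mean_spectral_lifetime()` averages valid lifetimes per channel over a
pixel mask, reporting channels with no valid pixel as missing (`NA`),
never 0 — a 0 would silently drag region comparisons; `roi_difference()`
subtracts two such profiles where both are defined.

## Rendering and mosaicking

- `wavelength_to_rgb()` is the classic piecewise-linear visible-spectrum
  approximation (hue ramps with break points at 440/490/510/580/645 nm,
  intensity roll-off below 420 and above 700 nm, display gamma 0.8), fixed
  in code so hues are bit-reproducible. Over 500–760 nm its hue angle
  moves monotonically from green to red.
- `render_color_image()` sums per-channel intensity × channel RGB into one
  triple per pixel and normalizes by the brightest component —
  configurable to a percentile (default the 100th, the true maximum; 99.9
  available for hot pixels). Opacity is total intensity over the maximum
  total (intensity-weighted transparency); the result is invariant under
  global intensity rescaling.
- `render_lifetime_image()` maps τ through viridis (perceptually ordered)
  over an explicit display range; opacity is the normalized intensity at
  the same wavelength, or its complement when inverted (which brings out
  low-count regions); invalid pixels are fully transparent. Normal and
  inverted opacities sum to 1 per pixel. A mosaic-wide maximum can be
  passed so tiles normalize against the whole image set.
- `stitch_tiles()` places tiles on the translation grid implied by the
  stage step and pixel pitch (row-major) and averages overlaps; pixels
  covered once are conserved exactly. No feathering or correlation-based
  registration: the emulated acquisitions are fixed-stage translations,
  and refining geometry the metadata already states would add failure
  modes without a model of stage error. The layout stores step and field
  of view and *derives* the overlap (e.g. 600 µm tiles stepped 500 µm
  overlap by 100 µm), because stated overlaps in acquisition notes are
  frequently rounded inconsistently with the geometry.

## Problem sizes and numerical tolerances used in the tests

The test suite runs simulations at 12–64 pixels square with 4–64 spectral
channels and 8–32 bins — sizes chosen so each property is exercised with
comfortable statistics while the whole suite stays interactive; the
headline recovery phantom is 64 × 64 pixels × 64 channels × 32 bins
(≈260k candidate decays, ≈41k fitted). Monte-Carlo assertions use fixed
seeds and 3–3.6 standard-error bands (the wider band where dozens of
per-bin comparisons share one assertion). Exact properties — count
conservation, mask monotonicity, rendering scale invariance, stitching
conservation, container round-trips — are asserted to machine precision.

## Known limitations

Single-exponential fitting only (multi-exponential or phasor analysis
would need a different estimator); no spectral unmixing; no registration
refinement in stitching; the simulator's Gaussian emission bands and
Gaussian IRF are idealizations; corrected cubes hold real values and are
not re-quantized, so the binary container stores only raw/decoded integer
cubes while corrected intermediates live in memory.
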