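Package: fsflim
Title: Simulation and Analysis of Full-Spectral Fluorescence Lifetime Imaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for full-spectral fluorescence lifetime imaging (FS-FLIM)
    photon-count cubes acquired by time-correlated single photon counting on
    spectrally dispersed line sensors. Provides a physics-based simulator of
    hyperspectral TCSPC image cubes (Gaussian emission profiles, IRF-convolved
    single-exponential decays, Poisson shot noise, dark counts, wavelength
    dependent detection efficiency, counter saturation and bin chaining), the
    matching correction chain (chained-bin decoding, dark-count subtraction,
    spectral flat-fielding), thresholded per-channel single-exponential
    lifetime fitting with spectral smoothing, per-wavelength lifetime
    histograms and region-of-interest summaries, spectral false-color and
    intensity-weighted lifetime rendering, and translation-grid tile
    mosaicking. Cubes are stored in a versioned binary container with a JSON
    header, with multi-page TIFF export for interoperability.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    png,
    tiff,
    viridisLite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
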