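#' Fluorophore description for phantom scenes
#'
#' A single emitting species with a Gaussian emission spectrum and a
#' mono-exponential excited-state lifetime. \code{brightness} is calibrated at
#' the sensor's peak-efficiency channel: the expected number of detected
#' photons per microsecond of dwell at unit mixing weight, before the
#' wavelength-dependent detection-efficiency roll-off.
#'
#' @param name Label used in provenance.
#' @param emission_center Emission peak, nm.
#' @param emission_fwhm Full width at half maximum of the emission band, nm.
#' @param lifetime_tau Excited-state lifetime, ns.
#' @param brightness Expected detected photons per microsecond dwell at unit
#'   weight (at peak detection efficiency).
#' @return An object of class \code{"fluorophore"}.
#' @export
fluorophore <- function(name, emission_center, emission_fwhm, lifetime_tau,
                        brightness) {
  if (lifetime_tau <= 0) stop("'lifetime_tau' must be positive", call. = FALSE)
  if (emission_fwhm <= 0) stop("'emission_fwhm' must be positive", call. = FALSE)
  if (brightness < 0) stop("'brightness' must be non-negative", call. = FALSE)
  structure(list(name = as.character(name),
                 emission_center = as.numeric(emission_center),
                 emission_fwhm = as.numeric(emission_fwhm),
                 lifetime_tau = as.numeric(lifetime_tau),
                 brightness = as.numeric(brightness)),
            class = "fluorophore")
}

#' Phantom scene: a spatial mixture of fluorophores
#'
#' Ground-truth scene for the simulator: a list of \code{\link{fluorophore}}s
#' and one non-negative per-pixel weight map per fluorophore. The expected
#' signal at a pixel is linear in the weights.
#'
#' @param fluorophores List of \code{\link{fluorophore}} objects.
#' @param weight_maps List of numeric matrices (one per fluorophore, identical
#'   extents, all values >= 0) giving per-pixel mixing weights.
#' @return An object of class \code{"phantom_scene"} with fields
#'   \code{rows}, \code{cols}, \code{fluorophores}, \code{weight_maps}.
#' @export
phantom_scene <- function(fluorophores, weight_maps) {
  if (length(fluorophores) != length(weight_maps))
    stop("need exactly one weight map per fluorophore", call. = FALSE)
  if (!all(vapply(fluorophores, inherits, logical(1), "fluorophore")))
    stop("'fluorophores' must be a list of fluorophore objects", call. = FALSE)
  d <- dim(weight_maps[[1]])
  for (w in weight_maps) {
    if (!is.matrix(w) || !identical(dim(w), d))
      stop("all weight maps must be matrices of identical extent", call. = FALSE)
    if (anyNA(w) || any(w < 0))
      stop("weights must be non-negative", call. = FALSE)
  }
  structure(list(rows = d[1], cols = d[2], fluorophores = fluorophores,
                 weight_maps = weight_maps),
            class = "phantom_scene")
}

#' Read a phantom scene from a YAML/JSON description
#'
#' The description holds a fluorophore table and, per fluorophore, either an
#' inline weight matrix or a path (relative to the description file) to a
#' grayscale PNG/TIFF weight image.
#'
#' @param path Scene description file (\code{.yaml}/\code{.yml}/\code{.json}).
#' @return A \code{\link{phantom_scene}}.
#' @export
read_phantom_scene <- function(path) {
  desc <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  base <- dirname(path)
  fls <- list(); wms <- list()
  for (f in desc$fluorophores) {
    fls[[length(fls) + 1L]] <- fluorophore(f$name, f$emission_center,
                                           f$emission_fwhm, f$lifetime_tau,
                                           f$brightness)
    w <- if (!is.null(f$weight_image)) {
      p <- file.path(base, f$weight_image)
      img <- if (grepl("\\.png$", p, ignore.case = TRUE)) png::readPNG(p)
             else tiff::readTIFF(p)
      if (length(dim(img)) == 3L) img <- img[, , 1]
      img
    } else {
      do.call(rbind, lapply(f$weights, unlist))
    }
    wms[[length(wms) + 1L]] <- w
  }
  phantom_scene(fls, wms)
}

#' Simulation parameters
#'
#' @param dwell_time Pixel dwell time, microseconds.
#' @param seed Integer seed; identical seed and inputs give a bit-identical cube.
#' @param include_dark Add dark counts to the expectation?
#' @param saturate Clip counts at the counter capacity?
#' @param chained Simulate chained (paired, 20-bit) bin counters?
#' @return An object of class \code{"sim_params"}.
#' @export
sim_params <- function(dwell_time = 500, seed = 1L, include_dark = TRUE,
                       saturate = TRUE, chained = FALSE) {
  if (dwell_time <= 0) stop("'dwell_time' must be positive", call. = FALSE)
  structure(list(dwell_time = as.numeric(dwell_time), seed = as.integer(seed),
                 include_dark = isTRUE(include_dark),
                 saturate = isTRUE(saturate), chained = isTRUE(chained)),
            class = "sim_params")
}

#' Gaussian emission profile integrated over spectral channels
#'
#' Per-channel weights of a fluorophore's Gaussian emission band: the Gaussian
#' density (mean \code{emission_center}, FWHM \code{emission_fwhm}) integrated
#' over each channel's half-open wavelength interval. Weights sum to the
#' fraction of the band inside the sensor range (at most 1); emission falling
#' outside the range is lost, as on the instrument.
#'
#' @param f A \code{\link{fluorophore}}.
#' @param axis A \code{\link{spectral_axis}}.
#' @return Numeric vector of length \code{axis$n_channels}.
#' @export
gaussian_emission_profile <- function(f, axis) {
  stopifnot(inherits(f, "fluorophore"), inherits(axis, "spectral_axis"))
  sigma <- f$emission_fwhm / (2 * sqrt(2 * log(2)))
  edges <- axis$lambda_min + (0:axis$n_channels) * axis$delta
  p <- stats::pnorm(edges, mean = f$emission_center, sd = sigma)
  diff(p)
}

#' Time-bin probabilities of an IRF-convolved exponential decay
#'
#' Probability that a detected photon falls in each time bin, for a
#' mono-exponential decay of lifetime \code{tau} convolved with a Gaussian
#' instrument response of the given FWHM (an exponentially modified Gaussian
#' arrival-time density, integrated analytically over each bin), renormalized
#' to sum to 1 over the observation window. The IRF is centered at
#' \code{t0_irf}; decay wrap-around across the laser period is neglected,
#' which for nanosecond lifetimes within a 50 ns period is a relative error
#' below \eqn{e^{-50/\tau}}.
#'
#' @param tau Lifetime, ns (> 0).
#' @param taxis A \code{\link{time_axis}}.
#' @param irf_fwhm Gaussian IRF full width at half maximum, picoseconds; 0
#'   gives the pure exponential.
#' @param t0_irf Center of the excitation pulse relative to the time axis
#'   origin, ns (default: the start of the window).
#' @return Numeric vector of length \code{taxis$n_bins} summing to 1.
#' @export
decay_bin_probabilities <- function(tau, taxis, irf_fwhm = 100, t0_irf = NULL) {
  stopifnot(inherits(taxis, "time_axis"))
  if (!is.finite(tau) || tau <= 0) stop("'tau' must be positive", call. = FALSE)
  if (is.null(t0_irf)) t0_irf <- taxis$t0_offset
  edges <- taxis$t0_offset + (0:taxis$n_bins) * taxis$bin_width
  sigma <- irf_fwhm * 1e-3 / (2 * sqrt(2 * log(2)))
  mass <- if (sigma <= 0) {
    # pure exponential: difference of survival functions, exact in the far
    # tail where the CDF form would cancel catastrophically
    s <- exp(-pmax(edges - t0_irf, 0) / tau)
    s[-length(s)] - s[-1]
  } else {
    diff(emg_cdf(edges, mu = t0_irf, sigma = sigma, tau = tau))
  }
  s <- sum(mass)
  if (s <= 0) stop("decay has no mass inside the observation window", call. = FALSE)
  mass / s
}

# CDF of the exponentially modified Gaussian (exponential decay of rate 1/tau
# convolved with N(mu, sigma^2)). Uses the log-scale form exp(log Phi + ...)
# to stay finite when the exponential prefactor overflows for small tau or
# large (t - mu).
emg_cdf <- function(t, mu, sigma, tau) {
  u <- (t - mu) / sigma
  v <- sigma / tau
  stats::pnorm(u) - exp(v^2 / 2 - u * v +
                          stats::pnorm(u - v, log.p = TRUE))
}

#' Expected-count cube of a phantom scene
#'
#' Noise-free forward model of the acquisition: at (row, col, channel k, bin j)
#' the expectation is the sum over fluorophores of
#' weight x brightness x dwell x emission_weight(k) x pde(k)/pde_peak x
#' decay_prob(j), plus a dark term dark_rate x dwell / n_bins uniform over bins
#' (and channels, unless a per-channel dark rate is supplied). Linear in the
#' weights and in the dwell time.
#'
#' @param scene A \code{\link{phantom_scene}}.
#' @param sensor A \code{\link{sensor_config}}.
#' @param saxis,taxis Spectral and time axes.
#' @param params A \code{\link{sim_params}}.
#' @return 4-D numeric array (rows, cols, n_channels, n_bins) of expectations.
#' @export
expected_count_cube <- function(scene, sensor, saxis, taxis, params) {
  stopifnot(inherits(scene, "phantom_scene"), inherits(sensor, "sensor_config"),
            inherits(params, "sim_params"))
  nk <- saxis$n_channels; nj <- taxis$n_bins
  pde_rel <- rep_len(sensor$pde_curve, nk) / sensor$pde_peak
  npix <- scene$rows * scene$cols
  # accumulate per-pixel spectral-temporal expectation as (npix x nk*nj)
  exp_kt <- matrix(0, npix, nk * nj)
  for (i in seq_along(scene$fluorophores)) {
    f <- scene$fluorophores[[i]]
    em <- gaussian_emission_profile(f, saxis) * pde_rel
    pt <- decay_bin_probabilities(f$lifetime_tau, taxis, sensor$irf_fwhm)
    kt <- as.vector(outer(em, pt))                       # length nk*nj
    w <- as.vector(scene$weight_maps[[i]]) * f$brightness * params$dwell_time
    exp_kt <- exp_kt + outer(w, kt)
  }
  if (params$include_dark) {
    dark_k <- rep_len(sensor$dark_count_rate, nk) * params$dwell_time * 1e-6 / nj
    exp_kt <- exp_kt + matrix(rep(dark_k, nj), npix, nk * nj, byrow = TRUE)
  }
  array(exp_kt, dim = c(scene$rows, scene$cols, nk, nj))
}

#' Simulate an FS-FLIM photon-count cube
#'
#' Draws independent Poisson counts from \code{\link{expected_count_cube}} and,
#' if \code{params$saturate}, clips each bin at the counter capacity
#' (\eqn{2^{10}-1} raw, \eqn{2^{20}-1} chained). The result is a valid
#' \code{\link{flim_cube}} carrying the scene and parameters in its provenance.
#' Identical seed and inputs give a bit-identical cube.
#'
#' @inheritParams expected_count_cube
#' @return A \code{\link{flim_cube}}.
#' @export
simulate_cube <- function(scene, sensor, saxis, taxis, params) {
  lambda <- expected_count_cube(scene, sensor, saxis, taxis, params)
  set.seed(params$seed)
  counts <- stats::rpois(length(lambda), as.vector(lambda))
  cap <- counter_capacity(sensor$bit_depth, chained = params$chained)
  if (params$saturate) counts <- pmin(counts, cap)
  else if (any(counts > cap))
    stop("simulated counts exceed counter capacity with saturation disabled",
         call. = FALSE)
  flim_cube(array(counts, dim = dim(lambda)),
            spectral_axis = saxis, time_axis = taxis,
            chained = params$chained, dwell_time = params$dwell_time,
            provenance = list(
              generator = "fsflim::simulate_cube",
              seed = params$seed,
              fluorophores = vapply(scene$fluorophores, `[[`, character(1), "name"),
              dark_count_rate = sensor$dark_count_rate,
              include_dark = params$include_dark,
              saturate = params$saturate))
}
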