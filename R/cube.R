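#' FS-FLIM photon-count cube
#'
#' The central container of the package: a 4-D array of non-negative integer
#' photon counts indexed (row, col, spectral channel, time bin), together with
#' its spectral and time axes, acquisition metadata and provenance.
#'
#' Per-bin counts are bounded by the sensor's histogram counter width:
#' \eqn{2^{10}-1 = 1023} in raw 10-bit mode, \eqn{2^{20}-1 = 1048575} when
#' adjacent bin counters are chained in pairs for extended dynamic range.
#'
#' @param counts 4-D numeric array of non-negative integers,
#'   dim = (rows, cols, n_channels, n_bins).
#' @param spectral_axis A \code{\link{spectral_axis}}; its \code{n_channels}
#'   must match \code{dim(counts)[3]}.
#' @param time_axis A \code{\link{time_axis}}; its \code{n_bins} must match
#'   \code{dim(counts)[4]}.
#' @param chained Logical; \code{TRUE} if bin counters were chained in pairs
#'   (20-bit capacity), \code{FALSE} for raw 10-bit counters.
#' @param dwell_time Pixel dwell (exposure) time in microseconds.
#' @param provenance Named list of free-text metadata.
#' @return An object of class \code{"flim_cube"}.
#' @seealso \code{\link{write_cube}}, \code{\link{simulate_cube}}
#' @export
flim_cube <- function(counts, spectral_axis, time_axis, chained = FALSE,
                      dwell_time = NA_real_, provenance = list()) {
  cube <- structure(
    list(counts = counts, spectral_axis = spectral_axis, time_axis = time_axis,
         chained = isTRUE(chained), dwell_time = as.numeric(dwell_time),
         provenance = provenance),
    class = "flim_cube")
  validate_flim_cube(cube)
  cube
}

#' Validate a flim_cube's invariants
#'
#' Checks dimensionality, axis agreement, non-negativity and the counter
#' capacity bound implied by the chaining mode. Called by the constructor and
#' the container reader.
#'
#' @param cube A \code{\link{flim_cube}}.
#' @return \code{cube}, invisibly; stops with an informative error on the first
#'   violated invariant.
#' @export
validate_flim_cube <- function(cube) {
  if (!inherits(cube, "flim_cube")) stop("not a flim_cube", call. = FALSE)
  d <- dim(cube$counts)
  if (is.null(d) || length(d) != 4L)
    stop("counts must be a 4-D array (row, col, channel, bin)", call. = FALSE)
  if (!inherits(cube$spectral_axis, "spectral_axis") ||
      !inherits(cube$time_axis, "time_axis"))
    stop("cube axes must be spectral_axis / time_axis objects", call. = FALSE)
  if (d[3] != cube$spectral_axis$n_channels)
    stop(sprintf("spectral extent (%d) != spectral_axis$n_channels (%d)",
                 d[3], cube$spectral_axis$n_channels), call. = FALSE)
  if (d[4] != cube$time_axis$n_bins)
    stop(sprintf("time extent (%d) != time_axis$n_bins (%d)",
                 d[4], cube$time_axis$n_bins), call. = FALSE)
  if (anyNA(cube$counts) || any(cube$counts < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (any(cube$counts != round(cube$counts)))
    stop("counts must be integers", call. = FALSE)
  cap <- counter_capacity(chained = cube$chained)
  if (any(cube$counts > cap))
    stop(sprintf("counts exceed the %s-mode counter capacity %d",
                 if (cube$chained) "chained (20-bit)" else "raw (10-bit)", cap),
         call. = FALSE)
  invisible(cube)
}

#' @export
print.flim_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<flim_cube> %d x %d pixels, %d spectral channels, %d time bins (%s)\n",
              d[1], d[2], d[3], d[4], if (x$chained) "chained" else "raw"))
  cat(sprintf("  spectral: %.6g-%.6g nm | time: %.6g ns bins | dwell: %g us\n",
              x$spectral_axis$lambda_min, x$spectral_axis$lambda_max,
              x$time_axis$bin_width, x$dwell_time))
  cat(sprintf("  total photons: %.0f\n", sum(x$counts)))
  invisible(x)
}

#' Sensor configuration
#'
#' Physical parameters of the SPAD line sensor and excitation laser that the
#' simulator and correction chain share: per-bin counter depth, dark-count
#' rate, wavelength-dependent photon detection efficiency (PDE) and the
#' temporal instrument response width.
#'
#' @param bit_depth Bits per histogram bin counter (10 for the raw mode).
#' @param dark_count_rate Dark counts per second per spectral channel; either a
#'   scalar or a per-channel vector.
#' @param pde_curve Detection probability per spectral channel in
#'   \code{[0, pde_peak]}; scalar (flat) or per-channel vector. Defaults to a
#'   flat curve at \code{pde_peak}.
#' @param pde_peak Peak detection efficiency (0.17 for the sensor emulated by
#'   the defaults).
#' @param irf_fwhm Full width at half maximum of the Gaussian instrument
#'   response, in picoseconds (laser pulse plus detector jitter).
#' @return An object of class \code{"sensor_config"}.
#' @export
sensor_config <- function(bit_depth = 10L, dark_count_rate = 0,
                          pde_curve = NULL, pde_peak = 0.17, irf_fwhm = 100) {
  if (!is.finite(pde_peak) || pde_peak <= 0 || pde_peak > 1)
    stop("'pde_peak' must be in (0, 1]", call. = FALSE)
  if (is.null(pde_curve)) pde_curve <- pde_peak
  if (any(pde_curve < 0) || any(pde_curve > pde_peak + 1e-12))
    stop("'pde_curve' must lie in [0, pde_peak]", call. = FALSE)
  if (any(dark_count_rate < 0))
    stop("'dark_count_rate' must be non-negative", call. = FALSE)
  structure(
    list(bit_depth = as.integer(bit_depth),
         dark_count_rate = as.numeric(dark_count_rate),
         pde_curve = as.numeric(pde_curve),
         pde_peak = as.numeric(pde_peak),
         irf_fwhm = as.numeric(irf_fwhm)),
    class = "sensor_config")
}

#' Per-bin counter capacity
#'
#' Maximum count a histogram bin can hold: \eqn{2^{b}-1} for a b-bit counter,
#' or \eqn{2^{2b}-1} when two counters are chained.
#'
#' @param bit_depth Counter bit depth (default 10).
#' @param chained Logical; chained counters double the effective bit depth.
#' @return The capacity as a double (1023 raw, 1048575 chained at 10 bits).
#' @export
counter_capacity <- function(bit_depth = 10L, chained = FALSE) {
  b <- if (isTRUE(chained)) 2L * as.integer(bit_depth) else as.integer(bit_depth)
  2^b - 1
}
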