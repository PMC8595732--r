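#' Spectral axis of an FS-FLIM sensor
#'
#' Describes the linear mapping between the spectral channels of a dispersed
#' line sensor and emission wavelength. Channels are uniform: channel \code{k}
#' (1-based) covers the half-open interval
#' \eqn{[\lambda_{min} + (k-1)\Delta\lambda,\; \lambda_{min} + k\Delta\lambda)}
#' with \eqn{\Delta\lambda = (\lambda_{max}-\lambda_{min})/n}.
#'
#' The default reproduces a 512-channel sensor spanning 500--760 nm, i.e. a
#' channel width of about 0.5 nm.
#'
#' @param n_channels Number of spectral channels (positive integer).
#' @param lambda_min,lambda_max Wavelength range covered by the sensor, in nm;
#'   \code{lambda_max} must exceed \code{lambda_min}.
#' @return An object of class \code{"spectral_axis"}: a list with fields
#'   \code{n_channels}, \code{lambda_min}, \code{lambda_max} and the derived
#'   channel width \code{delta} (nm).
#' @examples
#' ax <- spectral_axis()
#' ax$delta              # ~0.5 nm
#' wavelength_to_channel(ax, 550)
#' @export
spectral_axis <- function(n_channels = 512L, lambda_min = 500, lambda_max = 760) {
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 1L)
    stop("'n_channels' must be a positive integer", call. = FALSE)
  if (!is.finite(lambda_min) || !is.finite(lambda_max) || lambda_max <= lambda_min)
    stop("'lambda_max' must exceed 'lambda_min'", call. = FALSE)
  structure(
    list(n_channels = n_channels,
         lambda_min = as.numeric(lambda_min),
         lambda_max = as.numeric(lambda_max),
         delta = (lambda_max - lambda_min) / n_channels),
    class = "spectral_axis")
}

#' @export
print.spectral_axis <- function(x, ...) {
  cat(sprintf("<spectral_axis> %d channels, %.6g-%.6g nm (delta = %.6g nm)\n",
              x$n_channels, x$lambda_min, x$lambda_max, x$delta))
  invisible(x)
}

#' Channel center wavelengths
#'
#' @param axis A \code{\link{spectral_axis}}.
#' @return Numeric vector of length \code{axis$n_channels}: the wavelength (nm)
#'   at the center of each channel.
#' @export
channel_wavelengths <- function(axis) {
  stopifnot(inherits(axis, "spectral_axis"))
  axis$lambda_min + (seq_len(axis$n_channels) - 0.5) * axis$delta
}

#' Map a wavelength to its spectral channel
#'
#' Returns the 1-based index of the channel whose half-open interval contains
#' \code{lambda}. Wavelengths at or beyond \code{lambda_max}, or below
#' \code{lambda_min}, are out of range.
#'
#' @param axis A \code{\link{spectral_axis}}.
#' @param lambda Wavelength(s) in nm, each in \code{[lambda_min, lambda_max)}.
#' @return Integer channel index (vectorized over \code{lambda}).
#' @export
wavelength_to_channel <- function(axis, lambda) {
  stopifnot(inherits(axis, "spectral_axis"))
  if (any(lambda < axis$lambda_min | lambda >= axis$lambda_max))
    stop(sprintf("wavelength out of range [%g, %g)", axis$lambda_min, axis$lambda_max),
         call. = FALSE)
  k <- as.integer(floor((lambda - axis$lambda_min) / axis$delta)) + 1L
  # guard against floating-point landing exactly on the upper edge of the axis
  pmin(k, axis$n_channels)
}

#' Time axis of a TCSPC histogram
#'
#' Describes the arrival-delay binning of an on-chip TCSPC histogram. Bin
#' \code{j} (1-based) covers the half-open interval
#' \eqn{[t_0 + (j-1)w,\; t_0 + jw)} where \eqn{w} is \code{bin_width}.
#' The observation window \code{n_bins * bin_width} may not exceed the laser
#' period (50 ns at the 20 MHz repetition rate of the default).
#'
#' The default is 32 bins of 1.5625 ns spanning the full 50 ns period. Sensors
#' that chain bin counters in pairs use 16 bins of twice the width.
#'
#' @param n_bins Number of time bins (positive integer).
#' @param bin_width Bin width in ns.
#' @param t0_offset Delay of the first bin edge relative to the laser trigger, ns.
#' @param laser_period Laser repetition period in ns (50 ns = 20 MHz).
#' @return An object of class \code{"time_axis"}.
#' @export
time_axis <- function(n_bins = 32L, bin_width = 50 / 32, t0_offset = 0,
                      laser_period = 50) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L)
    stop("'n_bins' must be a positive integer", call. = FALSE)
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("'bin_width' must be positive", call. = FALSE)
  if (n_bins * bin_width > laser_period + 1e-9)
    stop("observation window n_bins * bin_width exceeds the laser period", call. = FALSE)
  structure(
    list(n_bins = n_bins, bin_width = as.numeric(bin_width),
         t0_offset = as.numeric(t0_offset), laser_period = as.numeric(laser_period)),
    class = "time_axis")
}

#' @export
print.time_axis <- function(x, ...) {
  cat(sprintf("<time_axis> %d bins x %.6g ns (t0 = %.6g ns, period = %.6g ns)\n",
              x$n_bins, x$bin_width, x$t0_offset, x$laser_period))
  invisible(x)
}

#' Bin center delays
#'
#' @param axis A \code{\link{time_axis}}.
#' @return Numeric vector of bin-center delays in ns.
#' @export
bin_times <- function(axis) {
  stopifnot(inherits(axis, "time_axis"))
  axis$t0_offset + (seq_len(axis$n_bins) - 0.5) * axis$bin_width
}
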