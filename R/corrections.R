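#' Corrected FS-FLIM cube
#'
#' Real-valued counterpart of a \code{\link{flim_cube}} produced by the
#' correction chain. Values stay non-negative (negative intermediates are
#' clipped to 0); the ordered \code{corrections_applied} tags guard against
#' double-correcting and record the pipeline order (dark subtraction before
#' spectral flat-fielding, which do not commute unless the efficiency curve is
#' flat).
#'
#' @param values 4-D numeric array (rows, cols, channels, bins), all >= 0
#'   (NA marks channels masked by a zero-efficiency flat-field).
#' @param spectral_axis,time_axis Axes inherited from the source cube.
#' @param dwell_time Dwell time, microseconds.
#' @param corrections_applied Ordered character vector of correction tags.
#' @param provenance Metadata list carried over from the source.
#' @return An object of class \code{"corrected_cube"}.
#' @export
corrected_cube <- function(values, spectral_axis, time_axis, dwell_time = NA_real_,
                           corrections_applied = character(), provenance = list()) {
  if (length(dim(values)) != 4L)
    stop("values must be a 4-D array", call. = FALSE)
  if (any(values < 0, na.rm = TRUE))
    stop("corrected values must be non-negative", call. = FALSE)
  if (anyDuplicated(corrections_applied))
    stop("duplicate correction tags", call. = FALSE)
  structure(list(values = values, spectral_axis = spectral_axis,
                 time_axis = time_axis, dwell_time = as.numeric(dwell_time),
                 corrections_applied = corrections_applied,
                 provenance = provenance),
            class = "corrected_cube")
}

#' @export
print.corrected_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<corrected_cube> %d x %d pixels, %d channels, %d bins; corrections: %s\n",
              d[1], d[2], d[3], d[4],
              if (length(x$corrections_applied)) paste(x$corrections_applied, collapse = " -> ")
              else "(none)"))
  invisible(x)
}

# promote a flim_cube to an (untagged) corrected_cube; pass corrected through
as_corrected <- function(x) {
  if (inherits(x, "corrected_cube")) return(x)
  validate_flim_cube(x)
  corrected_cube(x$counts + 0, x$spectral_axis, x$time_axis, x$dwell_time,
                 character(), x$provenance)
}

#' Decode chained time bins
#'
#' Merges adjacent bin pairs (2j-1, 2j) of a raw cube into single bins, as the
#' sensor's counter-chaining mode does on chip: counts are pairwise sums, the
#' merged bin covers the union interval (double width), and the capacity bound
#' becomes the 20-bit \eqn{2^{20}-1}. The grand total count is conserved.
#'
#' @param raw A \code{\link{flim_cube}} with an even number of time bins and
#'   \code{chained = FALSE}.
#' @return A \code{\link{flim_cube}} with half the bins and \code{chained = TRUE}.
#' @export
decode_chained <- function(raw) {
  validate_flim_cube(raw)
  if (raw$chained)
    stop("cube is already chained", call. = FALSE)
  nj <- raw$time_axis$n_bins
  if (nj %% 2L != 0L)
    stop("chained decoding requires an even number of time bins", call. = FALSE)
  d <- dim(raw$counts)
  merged <- array(raw$counts, dim = c(d[1] * d[2] * d[3], 2L, nj %/% 2L))
  merged <- merged[, 1L, , drop = FALSE] + merged[, 2L, , drop = FALSE]
  flim_cube(array(merged, dim = c(d[1], d[2], d[3], nj %/% 2L)),
            spectral_axis = raw$spectral_axis,
            time_axis = time_axis(nj %/% 2L, 2 * raw$time_axis$bin_width,
                                  raw$time_axis$t0_offset,
                                  raw$time_axis$laser_period),
            chained = TRUE, dwell_time = raw$dwell_time,
            provenance = c(raw$provenance, list(decoded_chained = TRUE)))
}

#' Subtract the expected dark-count background
#'
#' Removes the sensor dark contribution from every bin: dark counts are
#' uncorrelated with the laser, so their expectation
#' \code{dark_count_rate * dwell / n_bins} (rate in counts/s/channel, dwell in
#' microseconds) is uniform over time bins. Results are clipped at 0; the tag
#' \code{"dark"} is appended and re-application is an error.
#'
#' @param cube A \code{\link{flim_cube}} or \code{\link{corrected_cube}}.
#' @param sensor A \code{\link{sensor_config}} (scalar or per-channel
#'   \code{dark_count_rate}).
#' @param dwell Dwell time in microseconds; defaults to the cube's metadata.
#' @return A \code{\link{corrected_cube}} with tag \code{"dark"} appended.
#' @export
subtract_dark <- function(cube, sensor, dwell = NULL) {
  x <- as_corrected(cube)
  if ("dark" %in% x$corrections_applied)
    stop("dark subtraction already applied", call. = FALSE)
  if (is.null(dwell)) dwell <- x$dwell_time
  if (!is.finite(dwell) || dwell <= 0)
    stop("dwell time unavailable; pass 'dwell' explicitly", call. = FALSE)
  d <- dim(x$values)
  dark_k <- rep_len(sensor$dark_count_rate, d[3]) * dwell * 1e-6 / d[4]
  v <- sweep(x$values, 3L, dark_k, `-`)
  v[v < 0] <- 0
  corrected_cube(v, x$spectral_axis, x$time_axis, x$dwell_time,
                 c(x$corrections_applied, "dark"), x$provenance)
}

#' Flat-field the spectral detection-efficiency response
#'
#' Compensates the wavelength dependence of the sensor's photon detection
#' efficiency by dividing each channel by \code{pde_curve(k)/pde_peak}, the
#' multiplicative efficiency relative to the peak channel. Channels with zero
#' efficiency cannot be corrected and are masked to \code{NA} rather than
#' divided. The tag \code{"flatfield"} is appended; re-application is an error.
#'
#' @param cube A \code{\link{flim_cube}} or \code{\link{corrected_cube}}.
#' @param sensor A \code{\link{sensor_config}} whose \code{pde_curve} covers
#'   every channel.
#' @return A \code{\link{corrected_cube}} with tag \code{"flatfield"} appended.
#' @export
flatfield_spectral <- function(cube, sensor) {
  x <- as_corrected(cube)
  if ("flatfield" %in% x$corrections_applied)
    stop("spectral flat-field already applied", call. = FALSE)
  d <- dim(x$values)
  rel <- rep_len(sensor$pde_curve, d[3]) / sensor$pde_peak
  masked <- rel <= 0
  rel[masked] <- 1  # placeholder; masked channels are overwritten with NA
  v <- sweep(x$values, 3L, rel, `/`)
  if (any(masked)) v[, , masked, ] <- NA_real_
  corrected_cube(v, x$spectral_axis, x$time_axis, x$dwell_time,
                 c(x$corrections_applied, "flatfield"),
                 c(x$provenance,
                   if (any(masked)) list(masked_channels = which(masked))))
}
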