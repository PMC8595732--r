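#' Storage size of a full FS-FLIM cube
#'
#' Total number of bits needed to hold a complete photon-count cube at a given
#' word size per bin. At the full acquisition geometry (256 x 256 pixels, 512
#' spectral channels, 16 chained time bins, 32-bit words) this is
#' \eqn{2^{34}} bits = 16 Gib, the theoretical worst-case transfer size per
#' image.
#'
#' @param rows,cols Image extent in pixels.
#' @param n_channels Number of spectral channels.
#' @param n_bins Number of time bins.
#' @param word_bits Storage word size per bin counter, in bits.
#' @return Total size in bits (double, since the product overflows 32-bit
#'   integers at realistic geometries).
#' @examples
#' cube_storage_bits(256, 256, 512, 16, 32) / 2^30  # Gib
#' @export
cube_storage_bits <- function(rows, cols, n_channels, n_bins, word_bits) {
  args <- c(rows, cols, n_channels, n_bins, word_bits)
  if (any(args <= 0) || any(args != round(args)))
    stop("all arguments must be positive integers", call. = FALSE)
  as.numeric(rows) * cols * n_channels * n_bins * word_bits
}

#' Acquisition time of a raster scan
#'
#' Time to scan a full frame at a given per-pixel dwell, ignoring flyback:
#' rows x cols x dwell. A 256 x 256 frame at 85 us/pixel takes about 5.6 s.
#'
#' @param rows,cols Image extent in pixels.
#' @param dwell_us Pixel dwell time in microseconds.
#' @return Acquisition time in seconds.
#' @export
acquisition_time_s <- function(rows, cols, dwell_us) {
  if (any(c(rows, cols) <= 0) || dwell_us <= 0)
    stop("extents and dwell must be positive", call. = FALSE)
  rows * cols * dwell_us * 1e-6
}

#' Frame rate of a raster scan
#'
#' Reciprocal of \code{\link{acquisition_time_s}}: about 0.2 frames per second
#' for 256 x 256 pixels at 85 us dwell.
#'
#' @inheritParams acquisition_time_s
#' @return Frames per second.
#' @export
frame_rate_fps <- function(rows, cols, dwell_us) {
  1 / acquisition_time_s(rows, cols, dwell_us)
}

#' Candidate lifetime fits for a cube geometry
#'
#' Number of (pixel, spectral channel) decays a full per-channel lifetime
#' analysis must consider before thresholding: rows x cols x n_channels. A
#' 256 x 256 image with 512 channels yields 33,554,432 candidate fits.
#'
#' @param rows,cols Image extent in pixels.
#' @param n_channels Number of spectral channels.
#' @return Number of candidate fits (double).
#' @export
candidate_fit_count <- function(rows, cols, n_channels) {
  if (any(c(rows, cols, n_channels) <= 0))
    stop("all arguments must be positive", call. = FALSE)
  as.numeric(rows) * cols * n_channels
}
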