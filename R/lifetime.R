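#' Thresholding and smoothing policy for lifetime fitting
#'
#' Encodes the pixel-rejection rules applied before any decay is fitted: a
#' channel's total intensity at a pixel must reach both
#' \code{background_multiple} times the expected background (the "10 times the
#' background" rule) and an absolute photon floor (the 200-count rule for
#' tissue), plus the width and mode of the moving spectral mean used to rescue
#' low-signal spectral regions.
#'
#' @param background_multiple Signal-to-background multiple required
#'   (default 10, >= 1).
#' @param absolute_min_counts Absolute minimum photons per (pixel, channel)
#'   (default 200, >= 0).
#' @param smoothing_width Width of the moving spectral mean, in channels
#'   (default 8, i.e. about 4 nm at 0.5 nm channels).
#' @param smoothing_mode \code{"edges_only"} (default; smooth only channels
#'   whose image-mean intensity falls below \code{absolute_min_counts}, the
#'   low-signal spectral limits), \code{"full"} (smooth the whole spectrum) or
#'   \code{"off"}.
#' @return An object of class \code{"threshold_policy"}.
#' @export
threshold_policy <- function(background_multiple = 10, absolute_min_counts = 200,
                             smoothing_width = 8L,
                             smoothing_mode = c("edges_only", "full", "off")) {
  smoothing_mode <- match.arg(smoothing_mode)
  if (background_multiple < 1) stop("'background_multiple' must be >= 1", call. = FALSE)
  if (absolute_min_counts < 0) stop("'absolute_min_counts' must be >= 0", call. = FALSE)
  if (smoothing_width < 1) stop("'smoothing_width' must be >= 1", call. = FALSE)
  structure(list(background_multiple = as.numeric(background_multiple),
                 absolute_min_counts = as.numeric(absolute_min_counts),
                 smoothing_width = as.integer(smoothing_width),
                 smoothing_mode = smoothing_mode),
            class = "threshold_policy")
}

#' Per-(pixel, channel) intensity of a cube
#'
#' Sums the photon counts over time bins, the per-channel intensity image;
#' summing this again over channels gives the panchromatic intensity image.
#'
#' @param cube A \code{\link{flim_cube}} or \code{\link{corrected_cube}}.
#' @return 3-D numeric array (rows, cols, n_channels).
#' @export
channel_intensity <- function(cube) {
  v <- if (inherits(cube, "corrected_cube")) cube$values else cube$counts
  if (length(dim(v)) != 4L) stop("expected a 4-D cube", call. = FALSE)
  rowSums(v, dims = 3L)
}

#' Expected background level per (pixel, channel)
#'
#' The expected dark-count total collected in one pixel dwell in one spectral
#' channel (summed over time bins): \code{dark_count_rate * dwell * 1e-6}.
#' This is the reference level for the \code{background_multiple} threshold.
#'
#' @param sensor A \code{\link{sensor_config}}.
#' @param dwell Dwell time in microseconds.
#' @param n_channels Number of channels the level is expanded to.
#' @return Per-channel numeric vector of expected background counts.
#' @export
expected_background_level <- function(sensor, dwell, n_channels) {
  rep_len(sensor$dark_count_rate, n_channels) * dwell * 1e-6
}

#' Moving spectral mean
#'
#' Replaces each channel by the mean of a window of \code{width} channels
#' centered on it (for even widths the window extends one channel further to
#' the red side); at the spectrum edges the window truncates to the available
#' channels, so the result is the mean of a shorter window rather than a
#' padded one.
#'
#' @param values Per-channel numeric vector, or a matrix with channels in
#'   columns (each row smoothed independently).
#' @param width Window width in channels, between 1 and the number of channels.
#' @return Smoothed object of the same shape.
#' @export
moving_spectral_mean <- function(values, width) {
  vec <- is.null(dim(values))
  m <- if (vec) matrix(values, nrow = 1L) else as.matrix(values)
  nk <- ncol(m)
  width <- as.integer(width)
  if (width < 1L) stop("'width' must be >= 1", call. = FALSE)
  if (width > nk) stop("'width' exceeds the number of channels", call. = FALSE)
  left <- (width - 1L) %/% 2L
  right <- width - 1L - left
  out <- m
  for (k in seq_len(nk)) {
    lo <- max(1L, k - left); hi <- min(nk, k + right)
    out[, k] <- if (hi > lo) rowMeans(m[, lo:hi, drop = FALSE]) else m[, lo]
  }
  if (vec) as.vector(out) else out
}

# smooth a 4-D cube along the spectral dimension, per (pixel, bin)
smooth_cube_spectral <- function(values, width, channels = NULL) {
  d <- dim(values)
  perm <- aperm(values, c(1L, 2L, 4L, 3L))       # (row, col, bin, channel)
  m <- matrix(perm, ncol = d[3])
  sm <- moving_spectral_mean(m, width)
  if (!is.null(channels)) {                      # replace only selected channels
    keep <- m
    keep[, channels] <- sm[, channels]
    sm <- keep
  }
  aperm(array(sm, dim = d[c(1, 2, 4, 3)]), c(1L, 2L, 4L, 3L))
}

#' Threshold mask for lifetime fitting
#'
#' A (pixel, channel) qualifies for a lifetime fit when its intensity reaches
#' \code{background_multiple} times the per-channel background level AND the
#' absolute photon floor. Raising either threshold can only remove entries
#' (monotone). \code{NA} intensities (e.g. masked channels) never qualify.
#'
#' @param intensity 3-D array (rows, cols, channels) of per-channel counts.
#' @param background_level Per-channel expected background counts (scalar or
#'   vector, >= 0); see \code{\link{expected_background_level}}.
#' @param policy A \code{\link{threshold_policy}}.
#' @return Logical array of the same extent as \code{intensity}.
#' @export
threshold_mask <- function(intensity, background_level, policy) {
  stopifnot(inherits(policy, "threshold_policy"))
  if (any(background_level < 0)) stop("background level must be >= 0", call. = FALSE)
  d <- dim(intensity)
  bg <- rep_len(background_level, d[3])
  thr <- pmax(policy$background_multiple * bg, policy$absolute_min_counts)
  mask <- sweep(intensity, 3L, thr, `>=`)
  mask[is.na(mask)] <- FALSE
  mask
}

#' Fit a single-exponential decay to one TCSPC histogram
#'
#' Least-squares fit of \eqn{I(t) = A e^{-t/\tau} + B} to the per-bin counts,
#' over the bins from the histogram peak onward (tail fitting, which sidesteps
#' explicit IRF deconvolution). For fixed \eqn{\tau} the model is linear in
#' \eqn{(A, B)}, so those are solved in closed form and the profiled residual
#' sum of squares is minimized over \eqn{\tau} by a log-spaced scan followed by
#' Brent's method, bounded to \code{(0, laser_period]}. The fit is flagged
#' invalid (with \code{tau = 0}) when fewer than 3 tail bins hold positive
#' counts, the fitted amplitude is not positive, or the decay term does not
#' improve on a constant background.
#'
#' @param decay Per-bin real-valued counts (length \code{taxis$n_bins}).
#' @param taxis A \code{\link{time_axis}}.
#' @param weighted If \code{TRUE}, Poisson-weighted least squares with
#'   variances \code{max(counts, 1)}; default is unweighted.
#' @return An object of class \code{"decay_fit"}: list with \code{tau} (ns; 0
#'   if invalid), \code{amplitude}, \code{background}, \code{chi_square}
#'   (Pearson residual statistic), \code{n_photons}, \code{valid}.
#' @export
fit_single_exponential <- function(decay, taxis, weighted = FALSE) {
  stopifnot(inherits(taxis, "time_axis"))
  if (length(decay) != taxis$n_bins)
    stop("decay length does not match the time axis", call. = FALSE)
  fit_decay_tail(decay, bin_times(taxis), taxis$laser_period, weighted)
}

invalid_fit <- function(n_photons) {
  structure(list(tau = 0, amplitude = 0, background = 0, chi_square = NA_real_,
                 n_photons = n_photons, valid = FALSE),
            class = "decay_fit")
}

# closed-form (weighted) LS solve of y ~ A*x + B; returns c(A, B, rss)
solve_lin2 <- function(x, y, w) {
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x * x); sxy <- sum(w * x * y)
  det <- sxx * sw - sx * sx
  if (det <= .Machine$double.eps * sxx * sw)
    return(c(NA_real_, NA_real_, Inf))
  a <- (sxy * sw - sx * sy) / det
  b <- (sxx * sy - sx * sxy) / det
  if (a < 0 || b < 0) {
    # constrained refits on the boundary of {A >= 0, B >= 0}
    a1 <- max(sxy / sxx, 0); r1 <- sum(w * (y - a1 * x)^2)          # B = 0
    b2 <- max(sy / sw, 0);   r2 <- sum(w * (y - b2)^2)              # A = 0
    if (r1 <= r2) return(c(a1, 0, r1)) else return(c(0, b2, r2))
  }
  c(a, b, sum(w * (y - a * x - b)^2))
}

fit_decay_tail <- function(decay, t_centers, laser_period, weighted = FALSE) {
  n_photons <- sum(decay, na.rm = FALSE)
  if (anyNA(decay)) return(invalid_fit(NA_real_))
  peak <- which.max(decay)
  y <- decay[peak:length(decay)]
  tt <- t_centers[peak:length(decay)] - t_centers[peak]
  if (sum(y > 0) < 3L || length(y) < 3L) return(invalid_fit(n_photons))
  w <- if (weighted) 1 / pmax(y, 1) else rep(1, length(y))
  rss_tau <- function(tau) solve_lin2(exp(-tt / tau), y, w)[3]
  lo <- max(laser_period * 1e-4, diff(range(tt)) * 1e-3)
  grid <- exp(seq(log(lo), log(laser_period), length.out = 40L))
  rg <- vapply(grid, rss_tau, numeric(1))
  i <- which.min(rg)
  bracket <- c(grid[max(1L, i - 1L)], grid[min(length(grid), i + 1L)])
  tau <- if (bracket[1] < bracket[2])
    stats::optimize(rss_tau, interval = bracket, tol = 1e-10)$minimum
  else grid[i]
  sol <- solve_lin2(exp(-tt / tau), y, w)
  rss0 <- sum(w * (y - sum(w * y) / sum(w))^2)    # pure-background fit
  if (!is.finite(sol[3]) || sol[1] <= 0 || sol[3] >= rss0 * (1 - 1e-9))
    return(invalid_fit(n_photons))
  fitted <- sol[1] * exp(-tt / tau) + sol[2]
  structure(list(tau = tau, amplitude = sol[1], background = sol[2],
                 chi_square = sum((y - fitted)^2 / pmax(fitted, 1)),
                 n_photons = n_photons, valid = TRUE),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<decay_fit> tau = %.4g ns, A = %.4g, B = %.4g, chi2 = %.4g, %g photons\n",
                x$tau, x$amplitude, x$background, x$chi_square, x$n_photons))
  else cat("<decay_fit> invalid (tau reported as 0)\n")
  invisible(x)
}

#' Per-channel lifetime fitting of a corrected cube
#'
#' The full per-(pixel, channel) analysis: optionally applies the moving
#' spectral mean to the decays (per the policy's mode), computes per-channel
#' intensities, builds the threshold mask against the background level, and
#' fits a single-exponential lifetime to every surviving (pixel, channel)
#' decay. Rejected or failed entries carry \code{tau = 0}, so the support of
#' \code{tau_map} is contained in the mask (equal to it when every masked-in
#' decay admits a valid fit).
#'
#' @param cube A dark-subtracted \code{\link{corrected_cube}} (a raw
#'   \code{\link{flim_cube}} is accepted for dark-free simulations).
#' @param background_level Per-channel expected background counts; see
#'   \code{\link{expected_background_level}}.
#' @param policy A \code{\link{threshold_policy}}.
#' @param weighted Passed to \code{\link{fit_single_exponential}}.
#' @return An object of class \code{"lifetime_cube"}: \code{tau_map} and
#'   \code{intensity_map} (rows x cols x channels), the \code{policy},
#'   \code{n_attempted} and \code{n_valid} fit counts, and the axes.
#' @export
fit_cube <- function(cube, background_level, policy = threshold_policy(),
                     weighted = FALSE) {
  x <- as_corrected(cube)
  v <- x$values
  d <- dim(v)
  if (policy$smoothing_mode != "off") {
    chans <- if (policy$smoothing_mode == "full") seq_len(d[3])
    else {  # edges_only: channels whose image-mean intensity is low-signal
      chan_mean <- colMeans(matrix(channel_intensity(x), ncol = d[3]), na.rm = TRUE)
      which(chan_mean < policy$absolute_min_counts)
    }
    if (length(chans))
      v <- smooth_cube_spectral(v, policy$smoothing_width, chans)
  }
  intensity <- rowSums(v, dims = 3L)
  mask <- threshold_mask(intensity, background_level, policy)
  t_centers <- bin_times(x$time_axis)
  decays <- matrix(v, nrow = d[1] * d[2] * d[3], ncol = d[4])
  idx <- which(mask)
  tau_map <- array(0, dim = d[1:3])
  n_valid <- 0L
  for (i in idx) {
    fit <- fit_decay_tail(decays[i, ], t_centers, x$time_axis$laser_period, weighted)
    if (fit$valid) { tau_map[i] <- fit$tau; n_valid <- n_valid + 1L }
  }
  structure(list(tau_map = tau_map, intensity_map = intensity, policy = policy,
                 n_attempted = length(idx), n_valid = n_valid,
                 spectral_axis = x$spectral_axis, time_axis = x$time_axis,
                 dwell_time = x$dwell_time),
            class = "lifetime_cube")
}

#' @export
print.lifetime_cube <- function(x, ...) {
  d <- dim(x$tau_map)
  cat(sprintf("<lifetime_cube> %d x %d pixels x %d channels; %d fits attempted, %d valid\n",
              d[1], d[2], d[3], x$n_attempted, x$n_valid))
  invisible(x)
}

#' Lifetime histogram at one wavelength
#'
#' Distribution of the fitted lifetimes across the whole image at one spectral
#' channel, counting only valid (\eqn{\tau > 0}) pixels. Bins are half-open
#' \code{[edge_i, edge_{i+1})}; the total mass equals the number of valid
#' pixels whose lifetime falls inside the edge range.
#'
#' @param ltc A \code{\link{lifetime_cube}}.
#' @param channel Spectral channel index.
#' @param breaks Increasing vector of bin edges, ns.
#' @return List with \code{counts} (length \code{length(breaks) - 1}),
#'   \code{breaks}, \code{mids} and \code{n_valid}.
#' @export
lifetime_histogram <- function(ltc, channel, breaks) {
  stopifnot(inherits(ltc, "lifetime_cube"))
  if (channel < 1L || channel > dim(ltc$tau_map)[3])
    stop("channel out of range", call. = FALSE)
  if (is.unsorted(breaks, strictly = TRUE))
    stop("'breaks' must be strictly increasing", call. = FALSE)
  taus <- ltc$tau_map[, , channel]
  taus <- taus[taus > 0]
  bin <- findInterval(taus, breaks, rightmost.closed = FALSE)
  bin <- bin[bin >= 1L & bin <= length(breaks) - 1L]
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  list(counts = counts, breaks = breaks,
       mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
       n_valid = length(taus))
}

#' Mean spectral lifetime over a region of interest
#'
#' Per-channel mean of the valid fitted lifetimes over the pixels of a region
#' of interest, the "mean spectral lifetime" profile used to compare tissue
#' regions. Channels with no valid pixel in the ROI are reported as \code{NA}
#' (missing), never as 0.
#'
#' @param ltc A \code{\link{lifetime_cube}}.
#' @param roi Logical matrix (rows x cols) with at least one \code{TRUE} pixel.
#' @return Data frame with columns \code{channel}, \code{wavelength_nm},
#'   \code{mean_tau_ns}, \code{n_valid}.
#' @export
roi_mean_spectral_lifetime <- function(ltc, roi) {
  stopifnot(inherits(ltc, "lifetime_cube"))
  d <- dim(ltc$tau_map)
  if (!is.logical(roi) || !identical(dim(roi), d[1:2]))
    stop("'roi' must be a logical rows x cols matrix", call. = FALSE)
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  m <- matrix(ltc$tau_map, nrow = d[1] * d[2], ncol = d[3])[as.vector(roi), , drop = FALSE]
  n_valid <- colSums(m > 0)
  mean_tau <- ifelse(n_valid > 0, colSums(m) / pmax(n_valid, 1L), NA_real_)
  data.frame(channel = seq_len(d[3]),
             wavelength_nm = channel_wavelengths(ltc$spectral_axis),
             mean_tau_ns = mean_tau, n_valid = n_valid)
}

#' Difference between two ROI spectral-lifetime profiles
#'
#' Elementwise \code{a - b} of the per-channel mean lifetimes, defined only on
#' channels where both profiles are defined (\code{NA} elsewhere).
#'
#' @param a,b Data frames from \code{\link{roi_mean_spectral_lifetime}} on the
#'   same spectral axis.
#' @return Data frame with columns \code{channel}, \code{wavelength_nm},
#'   \code{delta_tau_ns}.
#' @export
roi_difference <- function(a, b) {
  if (!identical(a$channel, b$channel))
    stop("profiles are on different spectral axes", call. = FALSE)
  data.frame(channel = a$channel, wavelength_nm = a$wavelength_nm,
             delta_tau_ns = a$mean_tau_ns - b$mean_tau_ns)
}

#' Read a region-of-interest mask from a grayscale image
#'
#' Loads a PNG or TIFF label image and thresholds it into the logical pixel
#' mask \code{\link{roi_mean_spectral_lifetime}} expects; multi-channel images
#' use their first channel.
#'
#' @param path Path to a PNG or TIFF image.
#' @param threshold Gray level in [0, 1] at or above which a pixel belongs to
#'   the ROI.
#' @return Logical matrix (rows x cols).
#' @export
read_roi_mask <- function(path, threshold = 0.5) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
         else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img >= threshold
}

#' Export an ROI spectral-lifetime profile as CSV
#'
#' @param profile Data frame from \code{\link{roi_mean_spectral_lifetime}} or
#'   \code{\link{roi_difference}}.
#' @param path Output \code{.csv} path.
#' @return \code{path}, invisibly.
#' @export
write_roi_csv <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE)
  invisible(path)
}
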