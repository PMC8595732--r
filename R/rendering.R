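#' Map a wavelength to an RGB triple
#'
#' Deterministic piecewise-linear visible-spectrum approximation (the classic
#' Bruton map): linear hue ramps over 380--440--490--510--580--645--780 nm,
#' with an intensity roll-off below 420 nm and above 700 nm and a display
#' gamma. The map is fixed in code so rendered hues are bit-reproducible;
#' wavelengths outside the gamut return (0, 0, 0).
#'
#' @param lambda Wavelength(s), nm (vectorized).
#' @param gamma Display gamma applied to each component (default 0.8).
#' @param gamut Two-element range of renderable wavelengths, nm.
#' @return Numeric matrix with one row per wavelength and columns
#'   \code{r, g, b} in [0, 1].
#' @examples
#' wavelength_to_rgb(c(550, 650))
#' @export
wavelength_to_rgb <- function(lambda, gamma = 0.8, gamut = c(380, 780)) {
  n <- length(lambda)
  r <- g <- b <- numeric(n)
  s <- lambda >= 380 & lambda < 440
  r[s] <- (440 - lambda[s]) / 60; b[s] <- 1
  s <- lambda >= 440 & lambda < 490
  g[s] <- (lambda[s] - 440) / 50; b[s] <- 1
  s <- lambda >= 490 & lambda < 510
  g[s] <- 1; b[s] <- (510 - lambda[s]) / 20
  s <- lambda >= 510 & lambda < 580
  r[s] <- (lambda[s] - 510) / 70; g[s] <- 1
  s <- lambda >= 580 & lambda < 645
  r[s] <- 1; g[s] <- (645 - lambda[s]) / 65
  s <- lambda >= 645 & lambda <= 780
  r[s] <- 1
  fade <- rep(1, n)
  s <- lambda >= 380 & lambda < 420
  fade[s] <- 0.3 + 0.7 * (lambda[s] - 380) / 40
  s <- lambda > 700 & lambda <= 780
  fade[s] <- 0.3 + 0.7 * (780 - lambda[s]) / 80
  out <- cbind(r = r, g = g, b = b) * fade
  out <- out^gamma
  out[lambda < gamut[1] | lambda > gamut[2], ] <- 0
  out[lambda < 380 | lambda > 780, ] <- 0
  out
}

#' Rendered color image
#'
#' @param rgb Rows x cols x 3 array, components in [0, 1].
#' @param alpha Rows x cols matrix of opacities in [0, 1].
#' @param normalization Scalar the source intensities were divided by.
#' @return An object of class \code{"color_image"}.
#' @export
color_image <- function(rgb, alpha, normalization = 1) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("'rgb' must be rows x cols x 3", call. = FALSE)
  if (any(rgb < 0 | rgb > 1, na.rm = TRUE) || any(alpha < 0 | alpha > 1, na.rm = TRUE))
    stop("components must lie in [0, 1]", call. = FALSE)
  structure(list(rgb = rgb, alpha = alpha, normalization = normalization),
            class = "color_image")
}

#' Render a spectral intensity stack as a true-color image
#'
#' Assigns every spectral channel the RGB value of its center wavelength and
#' sums the per-channel contributions into one RGB triple per pixel, then
#' normalizes by the brightest component (optionally a percentile, for
#' hot-pixel robustness). Opacity is the intensity-weighted transparency:
#' per-pixel total intensity over the image (or mosaic) maximum. An all-zero
#' input renders as all-zero RGB with zero alpha.
#'
#' @param intensity 3-D array (rows, cols, channels) of per-channel counts
#'   (\code{NA}s are treated as 0).
#' @param axis The \code{\link{spectral_axis}} of the stack.
#' @param percentile Normalization percentile in (0, 100]; 100 (default) is the
#'   true maximum.
#' @param gamma Passed to \code{\link{wavelength_to_rgb}}.
#' @return A \code{\link{color_image}}.
#' @export
render_color_image <- function(intensity, axis, percentile = 100, gamma = 0.8) {
  stopifnot(inherits(axis, "spectral_axis"))
  d <- dim(intensity)
  if (length(d) != 3L || d[3] != axis$n_channels)
    stop("intensity extents do not match the spectral axis", call. = FALSE)
  intensity[is.na(intensity)] <- 0
  w <- wavelength_to_rgb(channel_wavelengths(axis), gamma = gamma)
  m <- matrix(intensity, ncol = d[3]) %*% w
  norm <- as.numeric(stats::quantile(m, percentile / 100, names = FALSE))
  if (norm <= 0)
    return(color_image(array(0, c(d[1], d[2], 3L)), matrix(0, d[1], d[2]), 0))
  rgb <- array(pmin(m / norm, 1), dim = c(d[1], d[2], 3L))
  tot <- rowSums(intensity, dims = 2L)
  alpha <- if (max(tot) > 0) tot / max(tot) else tot
  color_image(rgb, alpha, norm)
}

#' Render a lifetime map with intensity-weighted transparency
#'
#' Maps fitted lifetimes at one wavelength through a perceptually ordered
#' colormap (viridis) over \code{tau_range}, with per-pixel opacity equal to
#' the normalized fluorescence intensity at the same wavelength — or its
#' complement when \code{invert_alpha} is set, which brings out low-count
#' regions. Invalid pixels (\eqn{\tau = 0}) are fully transparent either way.
#'
#' @param tau Rows x cols matrix of fitted lifetimes, ns (0 = invalid).
#' @param intensity Rows x cols matrix of intensities at the same channel.
#' @param tau_range Two-element display range for \eqn{\tau}, ns; values are
#'   clamped to it.
#' @param invert_alpha Use \code{1 - normalized intensity} as opacity.
#' @param norm_max Intensity used as the normalization maximum; defaults to
#'   \code{max(intensity)}. Pass a mosaic-wide maximum to normalize a tile
#'   against the whole set of images.
#' @return A \code{\link{color_image}}.
#' @export
render_lifetime_image <- function(tau, intensity, tau_range, invert_alpha = FALSE,
                                  norm_max = NULL) {
  if (tau_range[1] >= tau_range[2])
    stop("'tau_range' must be an increasing range", call. = FALSE)
  if (!identical(dim(tau), dim(intensity)))
    stop("'tau' and 'intensity' extents differ", call. = FALSE)
  if (is.null(norm_max)) norm_max <- max(intensity, 0, na.rm = TRUE)
  pal <- grDevices::col2rgb(viridisLite::viridis(256L)) / 255
  u <- pmin(pmax((tau - tau_range[1]) / diff(tau_range), 0), 1)
  idx <- pmin(floor(u * 255) + 1L, 256L)
  d <- dim(tau)
  rgb <- array(t(pal[, idx]), dim = c(d[1], d[2], 3L))
  a <- if (norm_max > 0) pmin(intensity / norm_max, 1) else intensity * 0
  if (invert_alpha) a <- 1 - a
  a[tau <= 0] <- 0
  rgb[is.na(rgb)] <- 0; a[is.na(a)] <- 0
  color_image(rgb, a, norm_max)
}

#' Write a color image as PNG
#'
#' Exports the RGB channels plus the transparency channel as an RGBA PNG over
#' a black background convention (fully transparent pixels carry their RGB but
#' zero alpha).
#'
#' @param img A \code{\link{color_image}}.
#' @param path Output \code{.png} path.
#' @return \code{path}, invisibly.
#' @export
write_image_png <- function(img, path) {
  stopifnot(inherits(img, "color_image"))
  d <- dim(img$rgb)
  rgba <- array(0, dim = c(d[1], d[2], 4L))
  rgba[, , 1:3] <- img$rgb
  rgba[, , 4] <- img$alpha
  png::writePNG(rgba, path)
  invisible(path)
}
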