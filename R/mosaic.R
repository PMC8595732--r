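#' Translation-grid tile layout
#'
#' Geometry of a stage-translated tile scan: tiles are laid out on a regular
#' grid, row-major (first grid row left to right, then the next), with tile
#' origins \code{step} micrometers apart and each tile covering
#' \code{field_of_view} micrometers per side, so adjacent tiles overlap by
#' \code{field_of_view - step} micrometers. The overlap is derived from those
#' two numbers rather than stored separately.
#'
#' @param grid_rows,grid_cols Tile grid extents.
#' @param step Stage translation between tile origins, micrometers.
#' @param field_of_view Tile side length, micrometers.
#' @param pixel_pitch Micrometers per image pixel.
#' @return An object of class \code{"tile_layout"} (with derived fields
#'   \code{overlap} in micrometers and \code{step_px} in pixels).
#' @export
tile_layout <- function(grid_rows, grid_cols, step, field_of_view, pixel_pitch) {
  if (grid_rows < 1L || grid_cols < 1L)
    stop("grid extents must be positive", call. = FALSE)
  if (step > field_of_view)
    stop("'step' exceeds the field of view: tiles would not abut", call. = FALSE)
  if (pixel_pitch <= 0) stop("'pixel_pitch' must be positive", call. = FALSE)
  structure(list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
                 step = as.numeric(step), field_of_view = as.numeric(field_of_view),
                 pixel_pitch = as.numeric(pixel_pitch),
                 overlap = field_of_view - step,
                 step_px = as.integer(round(step / pixel_pitch))),
            class = "tile_layout")
}

#' @export
print.tile_layout <- function(x, ...) {
  cat(sprintf("<tile_layout> %d x %d tiles, step %g um (%d px), FOV %g um, overlap %g um\n",
              x$grid_rows, x$grid_cols, x$step, x$step_px, x$field_of_view, x$overlap))
  invisible(x)
}

#' Stitch image tiles into a mosaic
#'
#' Places the tiles on the translation grid (origins \code{step_px} pixels
#' apart, row-major order) and blends overlap regions by plain averaging;
#' pixels covered by a single tile are conserved exactly. Geometry is trusted
#' from the stage metadata — no registration refinement is attempted.
#'
#' @param tiles List of \code{grid_rows * grid_cols} numeric matrices (or
#'   rows x cols x k arrays, stitched per slice) of identical extent.
#' @param layout A \code{\link{tile_layout}}.
#' @param normalize If \code{TRUE}, divide the mosaic by its brightest pixel
#'   (via \code{\link{normalize_intensity}}) so intensities are comparable
#'   across the whole set of images.
#' @return Numeric matrix (or 3-D array) holding the mosaic; uncovered pixels
#'   (possible when \code{step_px} exceeds the tile extent) are 0.
#' @export
stitch_tiles <- function(tiles, layout, normalize = FALSE) {
  stopifnot(inherits(layout, "tile_layout"))
  if (length(tiles) != layout$grid_rows * layout$grid_cols)
    stop(sprintf("expected %d tiles for a %d x %d grid, got %d",
                 layout$grid_rows * layout$grid_cols, layout$grid_rows,
                 layout$grid_cols, length(tiles)), call. = FALSE)
  first <- tiles[[1]]
  d <- dim(first); if (length(d) == 2L) d <- c(d, 1L)
  for (tl in tiles)
    if (!identical(dim(tl)[1:2], d[1:2]))
      stop("all tiles must share the same pixel extent", call. = FALSE)
  sp <- layout$step_px
  out_r <- (layout$grid_rows - 1L) * sp + d[1]
  out_c <- (layout$grid_cols - 1L) * sp + d[2]
  acc <- array(0, dim = c(out_r, out_c, d[3]))
  cov <- matrix(0, out_r, out_c)
  i <- 0L
  for (gr in seq_len(layout$grid_rows)) {
    for (gc in seq_len(layout$grid_cols)) {
      i <- i + 1L
      rr <- (gr - 1L) * sp + seq_len(d[1])
      cc <- (gc - 1L) * sp + seq_len(d[2])
      tl <- array(tiles[[i]], dim = d)
      acc[rr, cc, ] <- acc[rr, cc, , drop = FALSE] + tl
      cov[rr, cc] <- cov[rr, cc] + 1
    }
  }
  covk <- array(rep(pmax(cov, 1), d[3]), dim = dim(acc))
  acc <- acc / covk
  out <- if (length(dim(first)) == 2L) acc[, , 1] else acc
  if (normalize) normalize_intensity(out) else out
}

#' Normalize intensities to the brightest pixel
#'
#' Divides by the image-wide maximum (or a percentile of it, for hot-pixel
#' robustness), clamping to [0, 1]; the normalization the mosaicking pipeline
#' applies across a whole set of images before rendering.
#'
#' @param x Numeric array of intensities.
#' @param percentile Percentile in (0, 100] defining the normalization level;
#'   100 (default) is the true maximum.
#' @return Array of the same shape with values in [0, 1] (all zeros if the
#'   input has no positive values).
#' @export
normalize_intensity <- function(x, percentile = 100) {
  m <- as.numeric(stats::quantile(x, percentile / 100, na.rm = TRUE, names = FALSE))
  if (!is.finite(m) || m <= 0) return(x * 0)
  pmin(x / m, 1)
}

#' Write a tile-layout JSON sidecar
#'
#' @param layout A \code{\link{tile_layout}}.
#' @param path Output \code{.json} path.
#' @return \code{path}, invisibly.
#' @export
write_layout_json <- function(layout, path) {
  stopifnot(inherits(layout, "tile_layout"))
  jsonlite::write_json(unclass(layout), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
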