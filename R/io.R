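# Single-file cube container: 8-byte magic, uint32 header length, UTF-8 JSON
# header (schema version, dims, axes, sensor-side metadata, provenance), then
# the counts as little-endian uint32 words in R array order. 32-bit words hold
# both raw (10-bit) and chained (20-bit) counts in one schema.

FSFLIM_MAGIC <- charToRaw("FSFLIMCB")
FSFLIM_SCHEMA_VERSION <- "1.0"

cube_header <- function(cube) {
  list(schema_version = FSFLIM_SCHEMA_VERSION,
       dims = dim(cube$counts),
       spectral_axis = list(n_channels = cube$spectral_axis$n_channels,
                            lambda_min = cube$spectral_axis$lambda_min,
                            lambda_max = cube$spectral_axis$lambda_max),
       time_axis = list(n_bins = cube$time_axis$n_bins,
                        bin_width = cube$time_axis$bin_width,
                        t0_offset = cube$time_axis$t0_offset,
                        laser_period = cube$time_axis$laser_period),
       chained = cube$chained,
       dwell_time = cube$dwell_time,
       provenance = cube$provenance,
       counts_dtype = "uint32le")
}

#' Write an FS-FLIM cube to its binary container
#'
#' Serializes a \code{\link{flim_cube}} losslessly to a versioned single-file
#' container: a magic string and schema version, a JSON header carrying the
#' axes and all metadata, and the counts as little-endian 32-bit words.
#' \code{\link{read_cube}} reproduces the cube bit-exactly.
#'
#' @param cube A valid \code{\link{flim_cube}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{read_cube}}, \code{\link{write_cube_tiff}},
#'   \code{\link{write_cube_json}}
#' @export
write_cube <- function(cube, path) {
  validate_flim_cube(cube)
  hdr <- jsonlite::toJSON(cube_header(cube), auto_unbox = TRUE, digits = NA, null = "null")
  hdr_raw <- charToRaw(as.character(hdr))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(FSFLIM_MAGIC, con)
  writeBin(length(hdr_raw), con, size = 4L, endian = "little")
  writeBin(hdr_raw, con)
  # counts fit in a signed 32-bit word (chained capacity is 2^20 - 1)
  writeBin(as.integer(cube$counts), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an FS-FLIM cube from its binary container
#'
#' Validates the magic string, schema version, declared extents against the
#' payload size, and every \code{\link{flim_cube}} invariant; any mismatch is a
#' format error naming the failed check rather than a silently corrupt cube.
#'
#' @param path Path to a file written by \code{\link{write_cube}}.
#' @return The reconstructed \code{\link{flim_cube}}.
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = length(FSFLIM_MAGIC))
  if (!identical(magic, FSFLIM_MAGIC))
    stop("format error: not an FS-FLIM cube container (bad magic)", call. = FALSE)
  hdr_len <- readBin(con, "integer", size = 4L, endian = "little")
  if (length(hdr_len) != 1L || is.na(hdr_len) || hdr_len <= 0L)
    stop("format error: corrupt header length", call. = FALSE)
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = hdr_len)),
                            simplifyVector = TRUE)
  if (!identical(hdr$schema_version, FSFLIM_SCHEMA_VERSION))
    stop(sprintf("format error: unsupported schema version '%s' (reader supports '%s')",
                 hdr$schema_version, FSFLIM_SCHEMA_VERSION), call. = FALSE)
  dims <- as.integer(hdr$dims)
  if (length(dims) != 4L || any(dims < 1L))
    stop("format error: declared dims are not a valid 4-D extent", call. = FALSE)
  if (dims[3] != hdr$spectral_axis$n_channels)
    stop("format error: spectral extent does not match declared n_channels", call. = FALSE)
  if (dims[4] != hdr$time_axis$n_bins)
    stop("format error: time extent does not match declared n_bins", call. = FALSE)
  n <- prod(dims)
  counts <- readBin(con, "integer", n = n + 1L, size = 4L, endian = "little")
  if (length(counts) != n)
    stop("format error: payload size does not match declared extents", call. = FALSE)
  flim_cube(array(counts, dim = dims),
            spectral_axis = spectral_axis(hdr$spectral_axis$n_channels,
                                          hdr$spectral_axis$lambda_min,
                                          hdr$spectral_axis$lambda_max),
            time_axis = time_axis(hdr$time_axis$n_bins, hdr$time_axis$bin_width,
                                  hdr$time_axis$t0_offset, hdr$time_axis$laser_period),
            chained = isTRUE(hdr$chained),
            dwell_time = if (is.null(hdr$dwell_time)) NA_real_ else hdr$dwell_time,
            provenance = as.list(hdr$provenance))
}

#' Export a cube's metadata as a JSON sidecar
#'
#' Writes the container header (axes, chaining mode, dwell, provenance) as
#' human-readable JSON for inspection without loading the counts.
#'
#' @param cube A \code{\link{flim_cube}}.
#' @param path Output \code{.json} path.
#' @return \code{path}, invisibly.
#' @export
write_cube_json <- function(cube, path) {
  validate_flim_cube(cube)
  jsonlite::write_json(cube_header(cube), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Export a cube as a multi-page TIFF
#'
#' Interoperability export: one 32-bit float page per (spectral channel, time
#' bin), channel-major, with counts scaled by the counter capacity so pages lie
#' in [0, 1] as TIFF viewers expect. Rounding \code{page * capacity} recovers
#' the integer counts exactly for both 10-bit and 20-bit (chained) data.
#'
#' @param cube A \code{\link{flim_cube}}.
#' @param path Output \code{.tif} path.
#' @param channels Spectral channels to export (default: all).
#' @return \code{path}, invisibly.
#' @export
write_cube_tiff <- function(cube, path, channels = NULL) {
  validate_flim_cube(cube)
  if (is.null(channels)) channels <- seq_len(cube$spectral_axis$n_channels)
  cap <- counter_capacity(chained = cube$chained)
  d <- dim(cube$counts)
  pages <- list()
  for (k in channels)
    for (j in seq_len(cube$time_axis$n_bins))
      pages[[length(pages) + 1L]] <- matrix(cube$counts[, , k, j], nrow = d[1]) / cap
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}
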