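# Raster input/output: single-channel elemental XRF maps as TIFF and the
# spatialized per-pixel CSV export.

#' Single-element XRF intensity map
#'
#' Container for one elemental intensity raster. Values are raw detector
#' counts (arbitrary units); the grid is row-major with pixel (0, 0) at the
#' top-left, `x` the column index and `z` the row index.
#'
#' @param values Numeric matrix of non-negative, finite intensities
#'   (rows = z, columns = x).
#' @param element Element label, e.g. `"Ca"` or `"Sr"`.
#' @param pixel_size_um Edge length of one pixel in micrometres (> 0).
#'
#' @return An object of class `element_map`: a list with fields `values`,
#'   `element` and `pixel_size_um`.
#' @examples
#' em <- element_map(matrix(runif(12, 0, 1e4), 3, 4), "Ca", 0.5)
#' dim(em$values)
#' @export
element_map <- function(values, element, pixel_size_um) {
  .assert(is.matrix(values) && is.numeric(values), "values must be a numeric matrix")
  .assert(all(is.finite(values)), "element map values must all be finite")
  .assert(all(values >= 0), "element map values must be non-negative")
  .assert(is.numeric(pixel_size_um) && length(pixel_size_um) == 1 && pixel_size_um > 0,
          "pixel_size_um must be a single positive number")
  structure(list(values = values, element = as.character(element),
                 pixel_size_um = as.numeric(pixel_size_um)),
            class = "element_map")
}

#' @export
print.element_map <- function(x, ...) {
  cat(sprintf("<element_map> %s, %d x %d px @ %.3g um/px, range [%.4g, %.4g]\n",
              x$element, nrow(x$values), ncol(x$values), x$pixel_size_um,
              min(x$values), max(x$values)))
  invisible(x)
}

# Minimal uncompressed little-endian single-strip TIFF writer for 32-bit
# IEEE float single-channel rasters. Needed because raw XRF counts exceed
# the [0, 1] range that integer-TIFF writers assume; the high dynamic
# range must be preserved verbatim.
#' @noRd
.write_tiff_float32 <- function(values, path) {
  nr <- nrow(values); nc <- ncol(values)
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  data_offset <- 8L
  data_bytes <- 4L * nr * nc
  ifd_offset <- data_offset + data_bytes
  # header
  writeBin(charToRaw("II"), con)
  w16(42L)
  w32(ifd_offset)
  # pixel data, row-major
  writeBin(as.numeric(t(values)), con, size = 4, endian = "little")
  # IFD: 10 entries
  entries <- list(
    c(256L, 4L, 1L, nc),          # ImageWidth
    c(257L, 4L, 1L, nr),          # ImageLength
    c(258L, 3L, 1L, 32L),         # BitsPerSample
    c(259L, 3L, 1L, 1L),          # Compression: none
    c(262L, 3L, 1L, 1L),          # Photometric: BlackIsZero
    c(273L, 4L, 1L, data_offset), # StripOffsets
    c(277L, 3L, 1L, 1L),          # SamplesPerPixel
    c(278L, 4L, 1L, nr),          # RowsPerStrip
    c(279L, 4L, 1L, data_bytes),  # StripByteCounts
    c(339L, 3L, 1L, 3L)           # SampleFormat: IEEE float
  )
  w16(length(entries))
  for (e in entries) {
    w16(e[1]); w16(e[2]); w32(e[3])
    if (e[2] == 3L) { w16(e[4]); w16(0L) } else w32(e[4])
  }
  w32(0L) # no next IFD
  invisible(path)
}

#' Write an element map as a 32-bit float TIFF
#'
#' Stores raw intensity values in a single-channel, uncompressed 32-bit
#' IEEE-float TIFF so the full dynamic range of the counts survives the
#' round trip. Values are stored at single precision.
#'
#' @param map An [element_map].
#' @param path Output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_element_map <- function(map, path) {
  .assert(inherits(map, "element_map"), "map must be an element_map")
  .write_tiff_float32(map$values, path)
  invisible(path)
}

#' Read a single-channel TIFF as an element map
#'
#' Values are loaded exactly as stored, with no rescaling. 8- and 16-bit
#' integer inputs are accepted but provoke a warning, since quantised
#' storage loses the high dynamic range of the raw counts.
#'
#' @param path TIFF file path.
#' @param element Element label attached to the map (e.g. `"Sr"`).
#' @param pixel_size_um Physical pixel size in micrometres.
#' @return An [element_map].
#' @export
read_element_map <- function(path, element, pixel_size_um) {
  .assert(file.exists(path), sprintf("file not found: %s", path))
  img <- tiff::readTIFF(path, info = TRUE)
  fmt <- attr(img, "sample.format")
  if (is.null(fmt) || !identical(fmt, "float")) {
    # integer storage: re-read raw counts instead of the [0, 1] rescaling
    info <- attributes(img)
    img <- tiff::readTIFF(path, as.is = TRUE)
    for (a in setdiff(names(info), c("dim"))) attr(img, a) <- info[[a]]
  }
  if (length(dim(img)) == 3L)
    stop(sprintf("expected single-channel TIFF, got %d channels: %s",
                 dim(img)[3], path), call. = FALSE)
  bits <- attr(img, "bits.per.sample")
  if (!is.null(bits) && bits < 32)
    warning(sprintf("%d-bit TIFF '%s': dynamic range may have been lost (32-bit float preferred)",
                    bits, basename(path)), call. = FALSE)
  vals <- matrix(as.numeric(img), nrow(img), ncol(img))
  if (any(vals < 0))
    stop(sprintf("negative intensities in '%s'", path), call. = FALSE)
  element_map(vals, element, pixel_size_um)
}

#' Write a zone label map as an 8-bit TIFF
#'
#' Encoding: 0 = background, 1 = Z1, 2 = Z2, 3 = Z3.
#'
#' @param zones A [zone label map][segment_zones] (`zone_map`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_zone_map <- function(zones, path) {
  .assert(inherits(zones, "zone_map"), "zones must be a zone_map")
  tiff::writeTIFF(zones$labels / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read an 8-bit zone label TIFF
#'
#' @param path TIFF path written by [write_zone_map()] (or an external
#'   manual segmentation with the same 0--3 encoding).
#' @param pixel_size_um Physical pixel size in micrometres.
#' @return A `zone_map` with provenance `"manual-override"`.
#' @export
read_zone_map <- function(path, pixel_size_um) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  .assert(length(dim(img)) == 2L, "zone map TIFF must be single-channel")
  labs <- matrix(as.integer(img), nrow(img), ncol(img))
  .assert(all(labs %in% 0:3), "zone labels must be in 0..3")
  new_zone_map(labs, pixel_size_um, provenance = "manual-override")
}

#' Export spatialized per-pixel Sr:Ca values as CSV
#'
#' One row per non-background pixel with 0-based cartesian pixel
#' coordinates (`x` = column, `z` = row, origin top-left), the Sr:Ca value
#' and the zone label, mirroring the spreadsheet-exchange surface used for
#' downstream frequency analysis.
#'
#' @param ratio A [ratio_map].
#' @param zones A `zone_map` congruent with `ratio`.
#' @param path Output CSV path.
#' @return Number of data rows written (header excluded), invisibly.
#' @export
export_spatialized_csv <- function(ratio, zones, path) {
  .assert(inherits(ratio, "ratio_map"), "ratio must be a ratio_map")
  .assert(inherits(zones, "zone_map"), "zones must be a zone_map")
  .assert(all(dim(ratio$values) == dim(zones$labels)),
          "ratio and zone maps have different shapes")
  keep <- which(zones$labels > 0L & ratio$valid)
  nr <- nrow(ratio$values)
  df <- data.frame(
    x = (keep - 1L) %/% nr,
    z = (keep - 1L) %% nr,
    srca_mmolmol = ratio$values[keep],
    zone = sprintf("Z%d", zones$labels[keep])
  )
  df <- df[order(df$z, df$x), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(nrow(df))
}
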