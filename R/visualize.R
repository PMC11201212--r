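# The two field renderings: cohort-normalised colour-LUT maps and the
# 3-3-2 RGB bit-slice conversion that exposes fine local Sr:Ca offsets.
# Rendering is read-only: no function here alters a ratio map.

#' Sr:Ca display lookup table
#'
#' 256-entry red - yellow - brown - cyan - slate-grey progression,
#' linearly interpolated between five anchors. The exact published
#' palette colours are not available, so the anchors are a documented
#' approximation; pass your own `anchors` (hex colours, low to high
#' index) to replace them. Index 255 is the background/maximum anchor.
#'
#' @param global_max_mmolmol Cohort-wide maximum Sr:Ca used for
#'   normalisation; stored with the LUT so one LUT renders a whole
#'   cohort on a common scale.
#' @param anchors Character vector of colours interpolated across the
#'   256 entries.
#' @return An object of class `colour_lut`: `colors` (256 x 3 matrix in
#'   [0, 1]) and `global_max_mmolmol`.
#' @export
srca_lut <- function(global_max_mmolmol = NULL,
                     anchors = c("#D7191C", "#FFD700", "#8B4513",
                                 "#00CED1", "#708090")) {
  .assert(length(anchors) >= 2, "need at least two anchor colours")
  ramp <- grDevices::colorRamp(anchors)(seq(0, 1, length.out = 256)) / 255
  structure(list(colors = ramp, global_max_mmolmol = global_max_mmolmol),
            class = "colour_lut")
}

#' Normalise a ratio map to 8-bit display indices
#'
#' Linear map of [0, `global_max`] onto [0, 255]. Background (invalid)
#' pixels are set to index 255, reproducing the background-anchoring
#' normalisation trick that keeps colours comparable across a cohort:
#' two maps rendered with the same `global_max` get identical colours
#' for identical values. Values above `global_max` are clipped with a
#' warning.
#'
#' @param ratio A calibrated [ratio_map][compute_ratio_map].
#' @param global_max Cohort-wide maximum Sr:Ca (mmol/mol), must be > 0.
#' @return Integer matrix of display indices in 0..255.
#' @export
normalize_for_display <- function(ratio, global_max) {
  .assert(inherits(ratio, "ratio_map"), "ratio must be a ratio_map")
  if (!is.numeric(global_max) || length(global_max) != 1 || global_max <= 0)
    stop("global_max must be a single positive number", call. = FALSE)
  v <- ratio$values
  vmax <- suppressWarnings(max(v[ratio$valid]))
  if (is.finite(vmax) && vmax > global_max) {
    warning(sprintf("map maximum %.4g exceeds global_max %.4g: clipping",
                    vmax, global_max), call. = FALSE)
  }
  idx <- matrix(255L, nrow(v), ncol(v))
  idx[ratio$valid] <- as.integer(round(255 * pmin(pmax(v[ratio$valid], 0), global_max) / global_max))
  idx
}

#' Apply a colour LUT to an 8-bit index raster
#'
#' Pure per-pixel table lookup.
#'
#' @param index Integer matrix with values in 0..255.
#' @param lut A [colour_lut][srca_lut].
#' @return Numeric array `nrow x ncol x 3` of RGB in [0, 1].
#' @export
apply_lut <- function(index, lut = srca_lut()) {
  .assert(inherits(lut, "colour_lut"), "lut must be a colour_lut")
  .assert(all(index >= 0 & index <= 255), "index values must be in 0..255")
  rgb <- lut$colors[index + 1L, , drop = FALSE]
  array(rgb, dim = c(nrow(index), ncol(index), 3L))
}

#' 3-3-2 RGB bit-slice conversion
#'
#' Splits each 8-bit display value into its three high bits (red), three
#' middle bits (green) and two low bits (blue), each rescaled to the
#' full 8-bit range (red/green by 255/7, blue by 255/3). Neighbouring
#' values that differ only slightly change only the low-order channel,
#' so subtle local Sr:Ca gradients become visible colour steps while
#' smooth regions stay smooth.
#'
#' @param index Integer matrix with values in 0..255.
#' @return Numeric array `nrow x ncol x 3` of RGB in [0, 1] (channel
#'   values are multiples of 1/255).
#' @export
convert_332_rgb <- function(index) {
  .assert(all(index >= 0 & index <= 255), "index values must be in 0..255")
  v <- index
  r3 <- v %/% 32L            # bits 7-5
  g3 <- (v %/% 4L) %% 8L     # bits 4-2
  b2 <- v %% 4L              # bits 1-0
  out <- array(0, dim = c(nrow(v), ncol(v), 3L))
  out[, , 1] <- round(r3 * 255 / 7) / 255
  out[, , 2] <- round(g3 * 255 / 7) / 255
  out[, , 3] <- round(b2 * 255 / 3) / 255
  out
}

# Burn a horizontal white scale bar into an RGB array (bottom-left).
#' @noRd
.burn_scalebar <- function(rgb, pixel_size_um, bar_um) {
  nr <- dim(rgb)[1]; nc <- dim(rgb)[2]
  len <- max(2L, round(bar_um / pixel_size_um))
  if (len >= nc - 10L) return(rgb)
  rows <- (nr - 9L):(nr - 7L)
  cols <- 6L:(5L + len)
  rgb[rows, cols, ] <- 1
  rgb
}

#' Render a ratio map to PNG
#'
#' @param ratio A calibrated [ratio_map][compute_ratio_map].
#' @param path Output PNG path.
#' @param global_max Cohort-wide maximum for normalisation; defaults to
#'   the map's own maximum (single-specimen scale).
#' @param mode `"lut"` for the Sr:Ca colour map, `"332"` for the 3-3-2
#'   RGB conversion.
#' @param lut Optional [colour_lut][srca_lut] for `mode = "lut"`.
#' @param scalebar_um Optional scale-bar length in micrometres burnt
#'   into the bottom-left corner (e.g. 50); `NULL` for none.
#' @return `path`, invisibly.
#' @export
render_map_png <- function(ratio, path, global_max = NULL,
                           mode = c("lut", "332"), lut = NULL,
                           scalebar_um = NULL) {
  mode <- match.arg(mode)
  if (is.null(global_max)) {
    global_max <- suppressWarnings(max(ratio$values[ratio$valid]))
    .assert(is.finite(global_max) && global_max > 0,
            "cannot infer global_max from an empty map")
  }
  idx <- normalize_for_display(ratio, global_max)
  rgb <- if (mode == "lut") {
    if (is.null(lut)) lut <- srca_lut(global_max)
    apply_lut(idx, lut)
  } else {
    convert_332_rgb(idx)
  }
  if (!is.null(scalebar_um))
    rgb <- .burn_scalebar(rgb, ratio$pixel_size_um, scalebar_um)
  png::writePNG(rgb, path)
  invisible(path)
}

#' Plot per-zone Sr:Ca frequency distributions
#'
#' Area-style frequency curves per zone (reporting view: bins at or
#' above the frequency threshold), on a shared Sr:Ca axis.
#'
#' @param x A [zone_stats][zone_histograms].
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.zone_stats <- function(x, ...) {
  cols <- c(Z1 = "#7EB6E8", Z2 = "#E69F00", Z3 = "#708090")
  xmax <- 0; ymax <- 0
  for (z in names(x$zones)) {
    s <- x$zones[[z]]
    if (!s$n) next
    sel <- !is.na(s$freq_reported)
    if (any(sel)) {
      xmax <- max(xmax, max(s$mids[sel]) + x$bin_width)
      ymax <- max(ymax, max(s$freq_reported[sel]))
    }
  }
  graphics::plot(NA, xlim = c(0, max(xmax, 1)), ylim = c(0, ymax * 1.05),
                 xlab = "Sr:Ca (mmol/mol)", ylab = "normalised frequency", ...)
  for (z in names(x$zones)) {
    s <- x$zones[[z]]
    if (!s$n) next
    y <- ifelse(is.na(s$freq_reported), 0, s$freq_reported)
    graphics::polygon(c(s$mids[1], s$mids, s$mids[length(s$mids)]), c(0, y, 0),
                      col = grDevices::adjustcolor(cols[z], alpha.f = 0.5),
                      border = cols[z])
  }
  graphics::legend("topright", legend = names(x$zones), fill = cols, bty = "n")
  invisible(x)
}

#' Plot a radial Sr:Ca transect
#'
#' @param x A [radial_transect][extract_transect].
#' @param boundaries Optional boundary radii (um from the core) drawn as
#'   dotted verticals on both sides.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.radial_transect <- function(x, boundaries = NULL, ...) {
  graphics::plot(x$positions_um, x$srca, type = "l",
                 xlab = "position along chord (um)",
                 ylab = "Sr:Ca (mmol/mol)", ...)
  graphics::abline(v = x$core_position_um, col = "red")
  if (!is.null(boundaries))
    graphics::abline(v = c(x$core_position_um - boundaries,
                           x$core_position_um + boundaries),
                     col = "red", lty = 3)
  invisible(x)
}
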