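# Per-zone Sr:Ca frequency distributions, summaries, marine-patch
# detection inside Z2, and a local-texture (granularity) index.

#' Per-zone Sr:Ca frequency distributions and summaries
#'
#' Histograms each zone's valid pixel values on a common grid of
#' `bin_width` mmol/mol bins starting at zero. Frequencies are
#' area-normalised per zone (count divided by the zone's valid pixel
#' count, so raw frequencies sum to 1 in every non-empty zone); the
#' reporting view additionally drops bins below `frequency_threshold`
#' (default 1\%) while the raw histogram is retained. The mode is the
#' centre of the maximal bin (ties resolved to the lower bin); mean and
#' max come from raw pixel values, not bins.
#'
#' @param ratio A calibrated [ratio_map][compute_ratio_map].
#' @param zones A congruent `zone_map`.
#' @param bin_width Histogram bin width in mmol/mol (default 0.25).
#' @param frequency_threshold Reporting threshold on normalised
#'   frequency (default 0.01).
#' @return An object of class `zone_stats`: per zone a list with
#'   `breaks`, `mids`, `freq` (raw), `freq_reported` (thresholded view,
#'   `NA` below threshold), `mode`, `mean`, `max`, `area_px`, `area_um2`;
#'   plus `bin_width`, `frequency_threshold`, `pixel_size_um`.
#' @export
zone_histograms <- function(ratio, zones, bin_width = 0.25,
                            frequency_threshold = 0.01) {
  .assert(inherits(ratio, "ratio_map"), "ratio must be a ratio_map")
  .assert(inherits(zones, "zone_map"), "zones must be a zone_map")
  .assert(all(dim(ratio$values) == dim(zones$labels)),
          "ratio and zone maps have different shapes")
  .assert(bin_width > 0, "bin_width must be > 0")
  vmax <- suppressWarnings(max(ratio$values[ratio$valid]))
  if (!is.finite(vmax)) vmax <- bin_width
  nb <- max(1L, ceiling(vmax / bin_width + 1e-9))
  breaks <- seq(0, nb * bin_width, by = bin_width)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  px <- zones$pixel_size_um
  per_zone <- lapply(1:3, function(z) {
    v <- ratio$values[ratio$valid & zones$labels == z]
    n <- length(v)
    if (n == 0L)
      return(list(breaks = breaks, mids = mids, freq = rep(NA_real_, nb),
                  freq_reported = rep(NA_real_, nb), n = 0L,
                  mode = NA_real_, mean = NA_real_, max = NA_real_,
                  area_px = 0L, area_um2 = 0))
    # bins are [lo, hi): a value exactly on a break goes to the upper bin
    bi <- pmin(nb, 1L + floor(v / bin_width))
    counts <- tabulate(bi, nb)
    freq <- counts / n
    rep_view <- ifelse(freq >= frequency_threshold, freq, NA_real_)
    list(breaks = breaks, mids = mids, freq = freq, freq_reported = rep_view,
         n = n, mode = mids[which.max(freq)], mean = mean(v), max = max(v),
         area_px = n, area_um2 = n * px^2)
  })
  names(per_zone) <- paste0("Z", 1:3)
  structure(list(zones = per_zone, bin_width = bin_width,
                 frequency_threshold = frequency_threshold,
                 pixel_size_um = px),
            class = "zone_stats")
}

#' Zone summary table (mode, mean, max, area)
#'
#' @param stats A [zone_stats][zone_histograms] object.
#' @return `data.frame` with columns `zone`, `mode`, `mean`, `max`,
#'   `area_px`, `area_um2`; missing values for empty zones.
#' @export
zone_summaries <- function(stats) {
  .assert(inherits(stats, "zone_stats"), "stats must be a zone_stats")
  do.call(rbind, lapply(names(stats$zones), function(z) {
    s <- stats$zones[[z]]
    data.frame(zone = z, mode = s$mode, mean = s$mean, max = s$max,
               area_px = s$area_px, area_um2 = s$area_um2)
  }))
}

#' @export
print.zone_stats <- function(x, ...) {
  cat(sprintf("<zone_stats> bin width %g mmol/mol, reporting threshold %g\n",
              x$bin_width, x$frequency_threshold))
  print(zone_summaries(x), row.names = FALSE)
  invisible(x)
}

#' Detect high-Sr marine patches inside Z2
#'
#' Patches are 8-connected components of Z2 pixels whose Sr:Ca exceeds
#' the marine threshold, filtered by a minimum area that suppresses
#' single-pixel speckle. The marine area fraction of Z2 is computed
#' before area filtering, so sub-minimum speckle still contributes to it.
#' Patches are sorted by area, largest first.
#'
#' @param ratio A calibrated [ratio_map][compute_ratio_map].
#' @param zones A congruent `zone_map`.
#' @param marine_threshold_mmolmol Marine Sr:Ca lower bound (default 6).
#' @param min_patch_area_um2 Minimum patch area (default 10 um^2).
#' @return An object of class `patch_set`: `patches` data.frame
#'   (`area_um2`, `centroid_x_um`, `centroid_z_um`, `max_srca`,
#'   `mean_srca`), `z2_marine_fraction`, thresholds, and the binary
#'   above-threshold mask.
#' @export
detect_patches <- function(ratio, zones, marine_threshold_mmolmol = 6,
                           min_patch_area_um2 = 10) {
  .assert(inherits(ratio, "ratio_map"), "ratio must be a ratio_map")
  .assert(inherits(zones, "zone_map"), "zones must be a zone_map")
  px <- ratio$pixel_size_um
  z2 <- ratio$valid & zones$labels == 2L
  above <- z2 & ratio$values > marine_threshold_mmolmol
  frac <- if (sum(z2) == 0L) NA_real_ else sum(above) / sum(z2)
  lab <- .label_components(above, connectivity = 8)
  nr <- nrow(lab)
  patches <- if (max(lab) > 0L) {
    do.call(rbind, lapply(seq_len(max(lab)), function(k) {
      i <- which(lab == k)
      data.frame(area_um2 = length(i) * px^2,
                 centroid_x_um = (mean((i - 1L) %/% nr) + 0.5) * px,
                 centroid_z_um = (mean((i - 1L) %% nr) + 0.5) * px,
                 max_srca = max(ratio$values[i]),
                 mean_srca = mean(ratio$values[i]))
    }))
  } else {
    data.frame(area_um2 = numeric(0), centroid_x_um = numeric(0),
               centroid_z_um = numeric(0), max_srca = numeric(0),
               mean_srca = numeric(0))
  }
  patches <- patches[patches$area_um2 >= min_patch_area_um2, , drop = FALSE]
  patches <- patches[order(-patches$area_um2), , drop = FALSE]
  rownames(patches) <- NULL
  structure(list(patches = patches,
                 z2_marine_fraction = frac,
                 marine_threshold_mmolmol = marine_threshold_mmolmol,
                 min_patch_area_um2 = min_patch_area_um2,
                 above_mask = above),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches > %g mmol/mol (min area %g um2), Z2 marine fraction %.3f\n",
              nrow(x$patches), x$marine_threshold_mmolmol,
              x$min_patch_area_um2, x$z2_marine_fraction))
  if (nrow(x$patches)) print(utils::head(x$patches, 10), row.names = FALSE)
  invisible(x)
}

#' Per-zone granularity index (median local coefficient of variation)
#'
#' Quantifies the granular texture of a zone as the median, over its
#' pixels, of the local standard deviation divided by the local mean in
#' a square window of the stated physical width. Scale-invariant: a
#' global rescaling of the map leaves the index unchanged.
#'
#' @param ratio A calibrated [ratio_map][compute_ratio_map].
#' @param zones A congruent `zone_map`.
#' @param window_um Window width in micrometres; must span at least
#'   3 pixels.
#' @return Named numeric vector `c(Z1 = , Z2 = , Z3 = )`; `NA` for empty
#'   zones.
#' @export
granularity_index <- function(ratio, zones, window_um = 5) {
  .assert(inherits(ratio, "ratio_map"), "ratio must be a ratio_map")
  px <- ratio$pixel_size_um
  w <- round(window_um / px)
  if (w < 3) stop("granularity window must span at least 3 pixels", call. = FALSE)
  if (w %% 2 == 0) w <- w + 1L
  v <- ifelse(ratio$valid, ratio$values, NA_real_)
  bs <- .box_sums(v, w)
  bs2 <- .box_sums(v^2, w)
  n <- bs$n
  mu <- bs$sum / pmax(n, 1L)
  varr <- pmax(bs2$sum / pmax(n, 1L) - mu^2, 0)
  cv <- sqrt(varr) / mu
  enough <- n >= ceiling(w^2 / 2) & mu > 0
  out <- sapply(1:3, function(z) {
    sel <- ratio$valid & zones$labels == z & enough
    if (!any(sel)) return(NA_real_)
    stats::median(cv[sel])
  })
  names(out) <- paste0("Z", 1:3)
  out
}
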