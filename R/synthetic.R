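# Synthetic otolith scan generator: paired Ca/Sr intensity maps over an
# elliptical otolith with three concentric Sr:Ca zones and analytic ground
# truth. The geometry uses similar concentric ellipses sharing the core as
# centre, so every zone boundary sits at a fixed fraction of the local
# otolith radius in any direction and true boundary radii are analytic.

#' Define a synthetic otolith scan scenario
#'
#' A scenario fixes the geometry, Sr:Ca zone levels, counting statistics
#' and optional texture of a simulated scan. Zone radii are expressed
#' along the major (x) semi-axis; zones are ellipses similar to the
#' otolith outline, so the Z1/Z2 and Z2/Z3 boundaries lie at constant
#' fractions `zone_radii_um / otolith_axes_um[1]` of the local radius.
#'
#' @param shape_px Integer `(rows, cols)` raster size in pixels.
#' @param pixel_size_um Pixel edge length, micrometres.
#' @param otolith_axes_um Semi-axes `(a_x, b_z)` of the elliptical otolith,
#'   micrometres.
#' @param core_xy_um Core position `(x, z)` in micrometres from the
#'   top-left pixel centre. Zones are concentric around the core.
#' @param otolith_center_um Centre of the otolith outline; defaults to
#'   the core, giving fully concentric geometry. An offset centre
#'   emulates the common real situation of a core displaced from the
#'   section centroid (used to exercise core refinement).
#' @param zone_radii_um Outer extent `(r1, r2)` of Z1 and Z2 along the x
#'   semi-axis, micrometres; Z3 extends to the otolith edge. Must be
#'   strictly increasing and strictly inside `otolith_axes_um[1]`.
#' @param zone_levels_mmolmol Sr:Ca level `(Z1, Z2, Z3)` in mmol/mol.
#'   With the identity calibration these numbers are also the Sr/Ca
#'   intensity ratios.
#' @param ca_intensity Mean Ca counts per otolith pixel. The default
#'   1e4 is an arbitrary count scale: absolute per-pixel count statistics
#'   are rarely published for beamline scans, so the default is a choice,
#'   not a measurement.
#' @param noise_model `list(type = "none")` for an exact noise-free scan,
#'   or `list(type = "poisson", dispersion = d)` for independent
#'   per-pixel counting noise with variance `d` times the mean.
#' @param patch_params Optional `list(n, radius_um = c(min, max), level,
#'   min_sep_um)`: hard discs of elevated Sr:Ca dropped inside Z2
#'   (clipped to Z2), centres kept `min_sep_um` apart edge-to-edge.
#' @param granularity_params Optional `list(amplitude, corr_length_um)`:
#'   multiplicative log-normal texture applied to Sr inside Z1 and Z2
#'   (unit mean; `amplitude` is the log-scale standard deviation).
#' @param ring_params Optional `list(amplitude, period_um, band_um)`:
#'   sinusoidal radial modulation of Sr in a band around the Z2/Z3
#'   boundary, emulating ring patterning at the marine--freshwater return.
#' @param seed Integer RNG seed; a fixed seed gives bit-identical rasters.
#'
#' @return An object of class `scan_scenario`.
#' @seealso [scan_preset()], [simulate_scan()]
#' @export
scan_scenario <- function(shape_px = c(400L, 600L),
                          pixel_size_um = 0.5,
                          otolith_axes_um = c(140, 90),
                          core_xy_um = c(150, 100),
                          otolith_center_um = NULL,
                          zone_radii_um = c(15, 90),
                          zone_levels_mmolmol = c(4, 8, 1.5),
                          ca_intensity = 1e4,
                          noise_model = list(type = "poisson", dispersion = 1),
                          patch_params = NULL,
                          granularity_params = NULL,
                          ring_params = NULL,
                          seed = 1L) {
  .assert(length(shape_px) == 2 && all(shape_px >= 8),
          "shape_px must be (rows, cols), both >= 8")
  .assert(pixel_size_um > 0, "pixel_size_um must be > 0")
  .assert(length(otolith_axes_um) == 2 && all(otolith_axes_um > 0),
          "otolith_axes_um must be two positive semi-axes")
  .assert(length(zone_radii_um) == 2,
          "zone_radii_um must give the outer radii of Z1 and Z2")
  if (!(zone_radii_um[1] > 0 && zone_radii_um[1] < zone_radii_um[2]))
    stop("zone_radii_um must be strictly increasing and positive", call. = FALSE)
  if (zone_radii_um[2] >= otolith_axes_um[1])
    stop(sprintf("zone_radii_um[2] (%g) must lie strictly inside otolith_axes_um[1] (%g)",
                 zone_radii_um[2], otolith_axes_um[1]), call. = FALSE)
  if (!is.null(otolith_center_um)) {
    off <- abs(core_xy_um - otolith_center_um)
    if (zone_radii_um[2] + off[1] >= otolith_axes_um[1] ||
        zone_radii_um[2] * otolith_axes_um[2] / otolith_axes_um[1] + off[2] >=
          otolith_axes_um[2])
      stop("zone_radii_um: outer zone does not fit inside the offset otolith outline",
           call. = FALSE)
  }
  .assert(length(zone_levels_mmolmol) == 3 && all(zone_levels_mmolmol >= 0),
          "zone_levels_mmolmol must be three non-negative Sr:Ca levels")
  .assert(ca_intensity > 0, "ca_intensity must be > 0")
  .assert(noise_model$type %in% c("none", "poisson"),
          "noise_model$type must be 'none' or 'poisson'")
  if (!is.null(patch_params)) {
    .assert(patch_params$n >= 0 && length(patch_params$radius_um) == 2 &&
              patch_params$level >= 0,
            "patch_params must give n, radius_um = c(min, max) and level")
    if (is.null(patch_params$min_sep_um)) patch_params$min_sep_um <- 4
  }
  structure(list(shape_px = as.integer(shape_px),
                 pixel_size_um = pixel_size_um,
                 otolith_axes_um = otolith_axes_um,
                 core_xy_um = core_xy_um,
                 otolith_center_um = otolith_center_um,
                 zone_radii_um = zone_radii_um,
                 zone_levels_mmolmol = zone_levels_mmolmol,
                 ca_intensity = ca_intensity,
                 noise_model = noise_model,
                 patch_params = patch_params,
                 granularity_params = granularity_params,
                 ring_params = ring_params,
                 seed = as.integer(seed)),
            class = "scan_scenario")
}

#' @export
print.scan_scenario <- function(x, ...) {
  cat(sprintf("<scan_scenario> %dx%d px @ %g um, zones (Z1 %.2f | Z2 %.2f | Z3 %.2f) mmol/mol, radii (%g, %g) um, noise %s, seed %d\n",
              x$shape_px[1], x$shape_px[2], x$pixel_size_um,
              x$zone_levels_mmolmol[1], x$zone_levels_mmolmol[2],
              x$zone_levels_mmolmol[3], x$zone_radii_um[1], x$zone_radii_um[2],
              x$noise_model$type, x$seed))
  if (!is.null(x$patch_params))
    cat(sprintf("  patches: n=%d level %.1f radius [%g, %g] um\n",
                x$patch_params$n, x$patch_params$level,
                x$patch_params$radius_um[1], x$patch_params$radius_um[2]))
  invisible(x)
}

#' Named scenario presets for the observed life-history phenotypes
#'
#' Each preset mirrors one of the Sr:Ca phenotypes seen in freshwater
#' pipefish otoliths. Levels with a documented range are drawn uniformly
#' from that range under `seed`, so a cohort of presets shows realistic
#' between-specimen variation:
#' \describe{
#'   \item{classic_amphidromous}{Z1 3--5, Z2 6--9, Z3 1--2 mmol/mol: the
#'     freshwater hatch / marine juvenile / freshwater adult pattern.}
#'   \item{patchy_amphidromous}{freshwater-level Z2 (2--3) carrying
#'     high-Sr discs at 7--10 mmol/mol: marine passage visible only as
#'     patches.}
#'   \item{freshwater_resident}{all zones below 4 mmol/mol, no patches.}
#'   \item{estuarine_hatch}{Z1 = 6, Z2 = 3, Z3 = 1 mmol/mol: high-salinity
#'     hatching signature with a freshwater juvenile phase.}
#'   \item{patchy_freshwaterZ2}{fixed Z2 level 3 with five discs at
#'     level 8: the controlled patch-recovery fixture.}
#'   \item{polynesian_extreme}{classic pattern with extreme Z2 patches up
#'     to ~16 mmol/mol.}
#' }
#'
#' @param name Preset name (see above).
#' @param seed Integer seed controlling level draws, patch placement and
#'   counting noise. Same name + seed gives an identical scenario.
#' @param ... Overrides passed to [scan_scenario()] (e.g. `shape_px`,
#'   `pixel_size_um`, `ca_intensity`, `noise_model`).
#' @return A `scan_scenario`.
#' @examples
#' sc <- scan_preset("classic_amphidromous", seed = 7)
#' sc$zone_levels_mmolmol
#' @export
scan_preset <- function(name, seed = 1L, ...) {
  presets <- c("classic_amphidromous", "patchy_amphidromous",
               "freshwater_resident", "estuarine_hatch",
               "patchy_freshwaterZ2", "polynesian_extreme")
  if (!name %in% presets)
    stop(sprintf("unknown preset '%s'; valid presets: %s",
                 name, paste(presets, collapse = ", ")), call. = FALSE)
  seed <- as.integer(seed)
  draws <- local({
    set.seed(seed)
    list(u = stats::runif(8))
  })
  runit <- function(i, lo, hi) lo + draws$u[i] * (hi - lo)
  args <- switch(name,
    classic_amphidromous = list(
      zone_levels_mmolmol = c(runit(1, 3, 5), runit(2, 6, 9), runit(3, 1, 2)),
      granularity_params = list(amplitude = 0.08, corr_length_um = 2),
      ring_params = list(amplitude = 0.08, period_um = 2.5, band_um = 8)),
    patchy_amphidromous = list(
      zone_levels_mmolmol = c(runit(1, 2.5, 3.5), runit(2, 2, 3), runit(3, 1, 2)),
      # patch geometry sized so the marine-signature area is conspicuous
      # (on the order of a tenth of Z2), as in the observed phenotype
      patch_params = list(n = 6L, radius_um = c(6, 12),
                          level = runit(4, 7, 10), min_sep_um = 6),
      granularity_params = list(amplitude = 0.08, corr_length_um = 2)),
    freshwater_resident = list(
      zone_levels_mmolmol = c(runit(1, 2, 3.5), runit(2, 2, 3.5), runit(3, 1, 2))),
    estuarine_hatch = list(
      zone_levels_mmolmol = c(6, 3, 1)),
    patchy_freshwaterZ2 = list(
      zone_levels_mmolmol = c(3, 3, 1.5),
      patch_params = list(n = 5L, radius_um = c(4, 7), level = 8,
                          min_sep_um = 6)),
    polynesian_extreme = list(
      zone_levels_mmolmol = c(runit(1, 3, 5), runit(2, 6, 9), runit(3, 1, 2)),
      patch_params = list(n = 6L, radius_um = c(4, 8),
                          level = runit(4, 12, 16), min_sep_um = 6),
      granularity_params = list(amplitude = 0.12, corr_length_um = 2))
  )
  args$seed <- seed
  do.call(scan_scenario, utils::modifyList(args, list(...)))
}

#' Generate a synthetic paired Ca/Sr scan with ground truth
#'
#' Builds the noise-free Ca dome over the elliptical otolith, multiplies
#' it by the per-pixel Sr:Ca level (zones, then patches, texture and
#' rings), applies counting noise, and returns both element maps together
#' with the analytic ground truth. With `noise_model$type = "none"` the
#' pixel-wise ratio Sr/Ca reproduces the zone levels exactly.
#'
#' @param scenario A [scan_scenario].
#' @return An object of class `otolith_scan`: list with `ca` and `sr`
#'   ([element_map]s) and `truth` (list with `zone_label_map` — integer
#'   matrix, 0 background, 1..3 zones — `patch_mask`, the true `core_px`
#'   (0-based x, z pixel coordinates), boundary fractions `f_boundaries`,
#'   and the generating `scenario`).
#' @examples
#' scan <- simulate_scan(scan_scenario(shape_px = c(60, 80),
#'   otolith_axes_um = c(18, 12), core_xy_um = c(20, 15),
#'   zone_radii_um = c(5, 12), noise_model = list(type = "none")))
#' table(scan$truth$zone_label_map)
#' @export
simulate_scan <- function(scenario) {
  .assert(inherits(scenario, "scan_scenario"), "scenario must be a scan_scenario")
  s <- scenario
  set.seed(s$seed)
  nr <- s$shape_px[1]; nc <- s$shape_px[2]; px <- s$pixel_size_um
  a <- s$otolith_axes_um[1]; b <- s$otolith_axes_um[2]
  # pixel-centre coordinates in um
  x <- (matrix(rep(0:(nc - 1L), each = nr), nr, nc) + 0.5) * px - s$core_xy_um[1]
  z <- (matrix(rep(0:(nr - 1L), times = nc), nr, nc) + 0.5) * px - s$core_xy_um[2]
  f <- sqrt((x / a)^2 + (z / b)^2)   # normalized elliptical radius around the core
  oc <- if (is.null(s$otolith_center_um)) s$core_xy_um else s$otolith_center_um
  xo <- x + s$core_xy_um[1] - oc[1]
  zo <- z + s$core_xy_um[2] - oc[2]
  f_out <- sqrt((xo / a)^2 + (zo / b)^2)
  inside <- f_out <= 1
  f1 <- s$zone_radii_um[1] / a
  f2 <- s$zone_radii_um[2] / a
  zone <- matrix(0L, nr, nc)
  zone[inside] <- 3L
  zone[inside & f <= f2] <- 2L
  zone[inside & f <= f1] <- 1L

  # Ca: gentle dome (smooth, near-uniform), empty background
  ca_clean <- ifelse(inside, s$ca_intensity * (1 - 0.1 * f_out^2), 0)

  # Sr:Ca level field
  level <- matrix(0, nr, nc)
  for (zz in 1:3) level[zone == zz] <- s$zone_levels_mmolmol[zz]

  patch_mask <- matrix(FALSE, nr, nc)
  n_placed <- 0L
  if (!is.null(s$patch_params) && s$patch_params$n > 0) {
    pp <- s$patch_params
    z2_idx <- which(zone == 2L)
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    tries <- 0L
    while (length(radii) < pp$n && tries < 500L) {
      tries <- tries + 1L
      pick <- z2_idx[sample.int(length(z2_idx), 1L)]
      cx <- x[pick]; cz <- z[pick]
      rr <- stats::runif(1, pp$radius_um[1], pp$radius_um[2])
      ok <- TRUE
      if (length(radii) > 0) {
        d <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cz)^2)
        ok <- all(d >= radii + rr + pp$min_sep_um)
      }
      if (ok) {
        centers <- rbind(centers, c(cx, cz))
        radii <- c(radii, rr)
      }
    }
    if (length(radii) < pp$n)
      warning(sprintf("placed %d of %d requested patches (Z2 too crowded)",
                      length(radii), pp$n), call. = FALSE)
    for (i in seq_along(radii)) {
      disc <- (x - centers[i, 1])^2 + (z - centers[i, 2])^2 <= radii[i]^2
      patch_mask <- patch_mask | (disc & zone == 2L)  # clipped to Z2
    }
    level[patch_mask] <- pp$level
    n_placed <- length(radii)
  }

  tex <- matrix(1, nr, nc)
  if (!is.null(s$granularity_params)) {
    gp <- s$granularity_params
    g <- matrix(stats::rnorm(nr * nc), nr, nc)
    g <- .gaussian_blur(g, gp$corr_length_um / px)
    g <- (g - mean(g)) / stats::sd(g)
    gmask <- zone %in% c(1L, 2L)
    tex[gmask] <- exp(gp$amplitude * g[gmask] - gp$amplitude^2 / 2)
  }
  if (!is.null(s$ring_params)) {
    rp <- s$ring_params
    rho <- f * a   # radial position in um along the major-axis parameter
    band <- inside & abs(rho - s$zone_radii_um[2]) <= rp$band_um
    tex[band] <- tex[band] *
      (1 + rp$amplitude * sin(2 * pi * (rho[band] - s$zone_radii_um[2]) / rp$period_um))
  }

  sr_clean <- ca_clean * level * tex

  if (s$noise_model$type == "poisson") {
    d <- if (is.null(s$noise_model$dispersion)) 1 else s$noise_model$dispersion
    # background carries a faint scatter floor so masks are estimated, not given
    ca_mean <- ca_clean + ifelse(inside, 0, 0.002 * s$ca_intensity)
    sr_mean <- sr_clean + ifelse(inside, 0, 0.002 * s$ca_intensity)
    ca_out <- matrix(stats::rpois(nr * nc, ca_mean / d) * d, nr, nc)
    sr_out <- matrix(stats::rpois(nr * nc, sr_mean / d) * d, nr, nc)
  } else {
    ca_out <- ca_clean
    sr_out <- sr_clean
  }

  structure(list(
    ca = element_map(ca_out, "Ca", px),
    sr = element_map(sr_out, "Sr", px),
    truth = list(zone_label_map = zone,
                 patch_mask = patch_mask,
                 n_patches = n_placed,
                 core_px = c(s$core_xy_um[1] / px - 0.5, s$core_xy_um[2] / px - 0.5),
                 f_boundaries = c(f1, f2),
                 scenario = s)
  ), class = "otolith_scan")
}

#' @export
print.otolith_scan <- function(x, ...) {
  s <- x$truth$scenario
  cat(sprintf("<otolith_scan> %dx%d px, %d otolith px, noise %s, seed %d\n",
              nrow(x$ca$values), ncol(x$ca$values),
              sum(x$truth$zone_label_map > 0), s$noise_model$type, s$seed))
  invisible(x)
}

#' Write a scenario as a plain-text YAML config
#'
#' Round-trippable with [read_scenario()]; used by the command-line
#' `simulate` entry point.
#'
#' @param scenario A [scan_scenario].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  .assert(inherits(scenario, "scan_scenario"), "scenario must be a scan_scenario")
  yaml::write_yaml(unclass(scenario), path, precision = 17L)
  invisible(path)
}

#' Read a scenario config written by [write_scenario()]
#' @param path YAML file path.
#' @return A `scan_scenario`.
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  for (fld in c("shape_px", "otolith_axes_um", "core_xy_um",
                "otolith_center_um", "zone_radii_um", "zone_levels_mmolmol"))
    if (!is.null(raw[[fld]])) raw[[fld]] <- as.numeric(unlist(raw[[fld]]))
  if (!is.null(raw$patch_params))
    raw$patch_params$radius_um <- as.numeric(unlist(raw$patch_params$radius_um))
  do.call(scan_scenario, raw)
}
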