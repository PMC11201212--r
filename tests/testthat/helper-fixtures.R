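# Shared fixtures: all synthetic, generated at test time.

# Small concentric scan: 160x120 px at 1 um, otolith 60x40 um,
# zone radii (10, 35) um, levels (Z1 3, Z2 8, Z3 2) mmol/mol.
tiny_scenario <- function(noise = "none", seed = 1, ...) {
  scan_scenario(shape_px = c(120L, 160L), pixel_size_um = 1,
                otolith_axes_um = c(60, 40), core_xy_um = c(80, 60),
                zone_radii_um = c(10, 35), zone_levels_mmolmol = c(3, 8, 2),
                ca_intensity = 1e4,
                noise_model = list(type = noise, dispersion = 1),
                seed = seed, ...)
}

tiny_scan <- function(noise = "none", seed = 1, ...)
  simulate_scan(tiny_scenario(noise = noise, seed = seed, ...))

# Presets at a reduced raster (1 um pixels) used for batch work.
small_args <- list(shape_px = c(220L, 320L), pixel_size_um = 1,
                   otolith_axes_um = c(140, 90), core_xy_um = c(160, 110),
                   zone_radii_um = c(15, 90))

small_preset_scan <- function(name, seed, ...)
  simulate_scan(do.call(scan_preset, c(list(name, seed = seed), small_args, list(...))))

# Calibrated ratio map + truth for a scan (identity calibration).
scan_ratio <- function(scan) {
  mask <- make_otolith_mask(scan$ca)
  calibrate(compute_ratio_map(scan$sr, scan$ca, mask))
}

# Zone map straight from the ground truth (no segmentation error).
truth_zone_map <- function(scan)
  zone_map(scan$truth$zone_label_map, scan$ca$pixel_size_um,
           provenance = "ground-truth")

jaccard <- function(a, b) sum(a & b) / sum(a | b)
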