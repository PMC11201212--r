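test_that("core detection: centroid, refinement on an offset core, override", {
  scan <- tiny_scan(noise = "poisson", seed = 2)
  ratio <- scan_ratio(scan)
  core <- detect_core(ratio)
  expect_lt(sqrt(sum((core - scan$truth$core_px)^2)), 2)
  # core offset 20 um from the section centroid, refinement on
  off <- simulate_scan(scan_scenario(
    shape_px = c(220L, 320L), pixel_size_um = 1, otolith_axes_um = c(140, 90),
    core_xy_um = c(140, 110), otolith_center_um = c(160, 110),
    zone_radii_um = c(15, 90), zone_levels_mmolmol = c(4, 8, 1.5), seed = 5))
  roff <- scan_ratio(off)
  refined <- detect_core(roff, method = "refine")
  expect_lt(sqrt(sum((refined - off$truth$core_px)^2)), 5)
  # centroid alone is ~20 px off: refinement is doing real work
  expect_gt(sqrt(sum((detect_core(roff) - off$truth$core_px)^2)), 10)
  ov <- detect_core(ratio, override = c(120, 80))
  expect_identical(as.numeric(ov), c(120, 80))
  expect_identical(attr(ov, "provenance"), "manual-override")
  empty <- ratio; empty$valid[] <- FALSE
  expect_error(detect_core(empty), "empty")
})

test_that("transects: constant maps, noise-free steps, raw-sampling oracle", {
  ca <- element_map(matrix(100, 40, 40), "Ca", 1)
  sr <- element_map(matrix(250, 40, 40), "Sr", 1)
  r <- calibrate(compute_ratio_map(sr, ca, matrix(TRUE, 40, 40)))
  tr <- extract_transect(r, c(20, 20), 30)
  expect_true(all(tr$srca == 2.5))
  expect_true(all(diff(tr$positions_um) > 0))

  scan <- tiny_scan(noise = "none")
  ratio <- scan_ratio(scan)
  tr2 <- extract_transect(ratio, scan$truth$core_px, 73, smoothing_um = 0)
  expect_true(all(tr2$srca %in% c(3, 8, 2)))

  # smoothing 0 equals a direct nearest-pixel lookup oracle
  core <- scan$truth$core_px
  th <- 37 * pi / 180
  k <- (-200):200
  xs <- core[1] + k * cos(th); zs <- core[2] + k * sin(th)
  keep <- xs >= -0.5 & xs <= ncol(ratio$values) - 0.5 &
          zs >= -0.5 & zs <= nrow(ratio$values) - 0.5
  vals <- rep(NA_real_, sum(keep))
  ri <- round(zs[keep]) + 1L; ci <- round(xs[keep]) + 1L
  for (i in seq_along(vals))
    if (ratio$valid[ri[i], ci[i]]) vals[i] <- ratio$values[ri[i], ci[i]]
  ok <- which(!is.na(vals))
  oracle <- vals[min(ok):max(ok)]
  tr3 <- extract_transect(ratio, core, 37, smoothing_um = 0)
  expect_identical(tr3$srca, oracle)
})

test_that("transects with too few valid samples are refused", {
  ca <- element_map(matrix(100, 30, 30), "Ca", 1)
  sr <- element_map(matrix(200, 30, 30), "Sr", 1)
  mask <- matrix(FALSE, 30, 30); mask[15, 10:20] <- TRUE
  r <- calibrate(compute_ratio_map(sr, ca, mask))
  expect_error(extract_transect(r, c(14, 14), 90), "10 valid samples")
})

test_that("change points on noise-free steps land within one sample", {
  scan <- tiny_scan(noise = "none")
  ratio <- scan_ratio(scan)
  tr <- extract_transect(ratio, scan$truth$core_px, 0, smoothing_um = 0)
  bd <- detect_zone_boundaries(tr)
  for (side in bd) {
    expect_length(side, 2)
    expect_lt(abs(side[1] - 10), 1.5)
    expect_lt(abs(side[2] - 35), 1.5)
  }
  # noisy recovery stays within 5 um of the truth
  noisy <- small_preset_scan("classic_amphidromous", seed = 7)
  rn <- scan_ratio(noisy)
  trn <- extract_transect(rn, noisy$truth$core_px, 0)
  bdn <- detect_zone_boundaries(trn)
  for (side in bdn) {
    expect_lt(abs(side[1] - 15), 5)
    expect_lt(abs(side[2] - 90), 5)
  }
})

test_that("constant transects admit no segmentation", {
  ca <- element_map(matrix(100, 40, 40), "Ca", 1)
  sr <- element_map(matrix(300, 40, 40), "Sr", 1)
  r <- calibrate(compute_ratio_map(sr, ca, matrix(TRUE, 40, 40)))
  tr <- extract_transect(r, c(20, 20), 0)
  expect_error(detect_zone_boundaries(tr), "manual thresholds")
})

test_that("piecewise-constant fit matches an exhaustive search oracle", {
  set.seed(77)
  y <- c(rnorm(8, 0), rnorm(7, 4), rnorm(9, 1))
  sse <- function(v) sum((v - mean(v))^2)
  best <- c(Inf, 0, 0)
  for (b1 in 1:(length(y) - 2)) for (b2 in (b1 + 1):(length(y) - 1)) {
    s <- sse(y[1:b1]) + sse(y[(b1 + 1):b2]) + sse(y[(b2 + 1):length(y)])
    if (s < best[1]) best <- c(s, b1, b2)
  }
  expect_identical(otolithxrf:::.pcw_segment(y, 3L), as.integer(best[2:3]))
})

test_that("segmentation recovers the true zones", {
  scan <- tiny_scan(noise = "none")
  ratio <- scan_ratio(scan)
  core <- detect_core(ratio)
  zm <- segment_zones(ratio, core)
  acc <- mean((zm$labels == scan$truth$zone_label_map)[scan$truth$zone_label_map > 0])
  expect_gte(acc, 0.98)
  noisy <- small_preset_scan("classic_amphidromous", seed = 3)
  rn <- scan_ratio(noisy)
  zn <- segment_zones(rn, detect_core(rn))
  for (z in 1:3)
    expect_gte(jaccard(zn$labels == z, noisy$truth$zone_label_map == z), 0.9)
})

test_that("zones partition the mask with radially ordered labels", {
  noisy <- small_preset_scan("estuarine_hatch", seed = 5)
  rn <- scan_ratio(noisy)
  core <- detect_core(rn)
  zm <- segment_zones(rn, core)
  expect_identical(unname(zm$labels > 0L), unname(rn$valid))
  nr <- nrow(zm$labels)
  mr <- sapply(1:3, function(z) {
    i <- which(zm$labels == z)
    mean(sqrt(((i - 1) %/% nr - core[1])^2 + ((i - 1) %% nr - core[2])^2))
  })
  expect_true(all(diff(mr) > 0))
})

test_that("weak-contrast freshwater residents still yield 3 ordered zones", {
  scan <- small_preset_scan("freshwater_resident", seed = 11)
  r <- scan_ratio(scan)
  zm <- segment_zones(r, detect_core(r))
  expect_true(all(tabulate(zm$labels[zm$labels > 0], 3) > 0))
})

test_that("radial and threshold methods agree on noise-free fixtures", {
  scan <- tiny_scan(noise = "none")
  ratio <- scan_ratio(scan)
  core <- detect_core(ratio)
  za <- segment_zones(ratio, core, method = "radial")
  zb <- segment_zones(ratio, core, method = "threshold")
  for (z in 1:3)
    expect_gte(jaccard(za$labels == z, zb$labels == z), 0.85)
  expect_match(zb$provenance, "threshold")
})

test_that("zone geometry: disc diameter, circularity, empty zones", {
  # circular otolith with a 12.5 um radius Z1 disc
  scan <- simulate_scan(scan_scenario(
    shape_px = c(120L, 120L), pixel_size_um = 1, otolith_axes_um = c(50, 50),
    core_xy_um = c(60, 60), zone_radii_um = c(12.5, 35),
    zone_levels_mmolmol = c(3, 8, 2), noise_model = list(type = "none"),
    seed = 1))
  geom <- zone_geometry(truth_zone_map(scan))
  z1 <- geom[geom$zone == "Z1", ]
  expect_lt(abs(z1$equiv_diameter_um - 25), 1)
  expect_gte(z1$circularity, 0.85)
  expect_lte(z1$circularity, 1.0)
  # empty Z2: reported as zero area, missing diameter, no crash
  labs <- scan$truth$zone_label_map
  labs[labs == 2L] <- 3L
  g2 <- zone_geometry(zone_map(labs, 1))
  expect_identical(g2[g2$zone == "Z2", "area_px"], 0L)
  expect_true(is.na(g2[g2$zone == "Z2", "equiv_diameter_um"]))
})
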