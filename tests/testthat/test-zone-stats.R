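# Helper: ratio map + zone map with prescribed values per zone label.
stub_ratio_zones <- function(values, labels, px = 1) {
  ca <- element_map(matrix(1000, nrow(values), ncol(values)), "Ca", px)
  sr <- element_map(values * 1000, "Sr", px)
  r <- calibrate(compute_ratio_map(sr, ca, labels > 0L))
  list(ratio = r, zones = zone_map(labels, px))
}

test_that("histogram definitions: single bin, symmetry, mode tie rule", {
  labs <- matrix(0L, 6, 6); labs[2:5, 2:5] <- 1L
  v <- matrix(0, 6, 6); v[labs == 1L] <- 2.0
  st <- zone_histograms(stub_ratio_zones(v, labs)$ratio,
                        zone_map(labs, 1), bin_width = 0.5)
  z1 <- st$zones$Z1
  expect_identical(sum(z1$freq > 0), 1L)
  expect_identical(max(z1$freq), 1)
  expect_identical(z1$mode, 2.25)  # centre of [2.0, 2.5)

  # half 2, half 8: two bins at 0.5, mean 5
  v2 <- v; v2[labs == 1L] <- rep(c(2, 8), each = 8)
  st2 <- zone_histograms(stub_ratio_zones(v2, labs)$ratio,
                         zone_map(labs, 1), bin_width = 0.5)
  expect_identical(sort(st2$zones$Z1$freq[st2$zones$Z1$freq > 0]), c(0.5, 0.5))
  expect_identical(st2$zones$Z1$mean, 5)
  # tie: the lower bin centre wins, deterministically
  expect_identical(st2$zones$Z1$mode, 2.25)
  expect_identical(zone_histograms(stub_ratio_zones(v2, labs)$ratio,
                                   zone_map(labs, 1), bin_width = 0.5)$zones$Z1$mode,
                   2.25)
})

test_that("raw frequencies sum to one and the reported view never gains bins", {
  scan <- tiny_scan(noise = "poisson", seed = 12)
  ratio <- scan_ratio(scan)
  zones <- truth_zone_map(scan)
  zones$labels[!ratio$valid] <- 0L
  st <- zone_histograms(ratio, zones)
  for (z in names(st$zones)) {
    s <- st$zones[[z]]
    expect_equal(sum(s$freq), 1, tolerance = 1e-9)
    expect_true(all(which(!is.na(s$freq_reported)) %in% which(s$freq > 0)))
    expect_gte(s$freq[which(s$mids == s$mode)], max(s$freq) - 1e-12)
  }
})

test_that("histograms match an independent tally of the CSV export", {
  scan <- tiny_scan(noise = "poisson", seed = 13)
  ratio <- scan_ratio(scan)
  zones <- truth_zone_map(scan)
  zones$labels[!ratio$valid] <- 0L
  st <- zone_histograms(ratio, zones, bin_width = 0.25)
  f <- withr::local_tempfile(fileext = ".csv")
  export_spatialized_csv(ratio, zones, f)
  df <- read.csv(f)
  for (z in c("Z1", "Z2", "Z3")) {
    v <- df$srca_mmolmol[df$zone == z]
    nb <- length(st$zones[[z]]$mids)
    tally <- tabulate(pmin(nb, 1L + floor(v / 0.25)), nb)
    expect_equal(st$zones[[z]]$freq, tally / length(v), tolerance = 1e-12)
  }
})

test_that("union histogram is the pixel-weighted mixture of zone histograms", {
  scan <- tiny_scan(noise = "poisson", seed = 14)
  ratio <- scan_ratio(scan)
  zones <- truth_zone_map(scan)
  zones$labels[!ratio$valid] <- 0L
  st <- zone_histograms(ratio, zones)
  union_labels <- zones$labels
  union_labels[union_labels > 0L] <- 1L
  stu <- zone_histograms(ratio, zone_map(union_labels, 1))
  ns <- sapply(st$zones, `[[`, "n")
  mix <- Reduce(`+`, lapply(1:3, function(z) st$zones[[z]]$freq * ns[z])) / sum(ns)
  expect_equal(stu$zones$Z1$freq, mix, tolerance = 1e-12)
})

test_that("empty zones propagate missing summaries", {
  labs <- matrix(0L, 6, 6); labs[2:5, 2:5] <- 3L
  v <- matrix(0, 6, 6); v[labs > 0] <- 1.5
  st <- zone_histograms(stub_ratio_zones(v, labs)$ratio, zone_map(labs, 1))
  expect_true(is.na(st$zones$Z1$mode))
  expect_identical(st$zones$Z1$area_px, 0L)
  sm <- zone_summaries(st)
  expect_true(is.na(sm$mean[sm$zone == "Z1"]))
  expect_false(is.na(sm$mode[sm$zone == "Z3"]))
})

test_that("Z3 separates from the Z2 marine component on classic patterns", {
  scan <- small_preset_scan("classic_amphidromous", seed = 6)
  ratio <- scan_ratio(scan)
  zones <- truth_zone_map(scan)
  zones$labels[!ratio$valid] <- 0L
  st <- zone_histograms(ratio, zones)
  z3_support <- max(st$zones$Z3$mids[st$zones$Z3$freq > 0])
  z2_marine <- st$zones$Z2$mids[st$zones$Z2$freq >= 0.01 & st$zones$Z2$mids > 6]
  expect_gt(length(z2_marine), 0)
  expect_lt(z3_support, min(z2_marine))
})

test_that("patch detection: full marine Z2, resident, and disc recovery", {
  classic <- tiny_scan(noise = "none")
  rc <- scan_ratio(classic)
  zc <- truth_zone_map(classic)
  ps <- detect_patches(rc, zc)
  expect_identical(nrow(ps$patches), 1L)
  expect_equal(ps$z2_marine_fraction, 1)
  expect_equal(ps$patches$area_um2[1], sum(zc$labels == 2L))

  resident <- small_preset_scan("freshwater_resident", seed = 2)
  rr <- scan_ratio(resident)
  pr <- detect_patches(rr, truth_zone_map(resident))
  expect_identical(nrow(pr$patches), 0L)
  expect_lt(pr$z2_marine_fraction, 0.01)

  patchy <- small_preset_scan("patchy_freshwaterZ2", seed = 4)
  rp <- scan_ratio(patchy)
  pp <- detect_patches(rp, truth_zone_map(patchy))
  expect_identical(nrow(pp$patches), patchy$truth$n_patches)
  expect_lt(abs(sum(pp$patches$area_um2) - sum(patchy$truth$patch_mask)) /
              sum(patchy$truth$patch_mask), 0.1)
  expect_true(all(diff(pp$patches$area_um2) <= 0))
})

test_that("patch components use 8-connectivity", {
  labs <- matrix(0L, 8, 8); labs[2:7, 2:7] <- 2L
  v <- matrix(2, 8, 8)
  v[3, 3] <- 8; v[4, 4] <- 8   # diagonal contact: one patch
  sz <- stub_ratio_zones(v, labs)
  ps <- detect_patches(sz$ratio, sz$zones, min_patch_area_um2 = 0)
  expect_identical(nrow(ps$patches), 1L)
})

test_that("granularity index orders texture amplitudes and is scale-free", {
  labs <- matrix(0L, 40, 40); labs[5:36, 5:36] <- 2L
  base <- matrix(3, 40, 40)
  sz0 <- stub_ratio_zones(base, labs)
  g0 <- granularity_index(sz0$ratio, sz0$zones)
  expect_equal(unname(g0["Z2"]), 0)
  set.seed(55)
  noise <- matrix(rnorm(1600), 40, 40)
  lo <- base * exp(0.1 * noise); hi <- base * exp(0.3 * noise)
  szl <- stub_ratio_zones(lo, labs); szh <- stub_ratio_zones(hi, labs)
  gl <- granularity_index(szl$ratio, szl$zones)
  gh <- granularity_index(szh$ratio, szh$zones)
  expect_gt(gh["Z2"], gl["Z2"])
  sz5 <- stub_ratio_zones(lo * 5, labs)
  expect_equal(granularity_index(sz5$ratio, sz5$zones)["Z2"], gl["Z2"],
               tolerance = 1e-9)
  expect_error(granularity_index(szl$ratio, szl$zones, window_um = 2), "3 pixels")
})
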