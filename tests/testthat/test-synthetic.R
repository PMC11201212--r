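test_that("noise-free construction reproduces zone levels exactly", {
  scan <- tiny_scan(noise = "none")
  zl <- scan$truth$zone_label_map
  ratio <- matrix(0, nrow(zl), ncol(zl))
  inside <- zl > 0
  ratio[inside] <- scan$sr$values[inside] / scan$ca$values[inside]
  for (z in 1:3)
    expect_equal(unname(ratio[zl == z]),
                 rep(tiny_scenario()$zone_levels_mmolmol[z], sum(zl == z)),
                 tolerance = 1e-12)
  # background carries no signal in the noise-free case
  expect_true(all(scan$ca$values[!inside] == 0))
})

test_that("a fixed seed gives bit-identical rasters", {
  s1 <- tiny_scan(noise = "poisson", seed = 42)
  s2 <- tiny_scan(noise = "poisson", seed = 42)
  expect_identical(s1$ca$values, s2$ca$values)
  expect_identical(s1$sr$values, s2$sr$values)
  s3 <- tiny_scan(noise = "poisson", seed = 43)
  expect_false(identical(s1$sr$values, s3$sr$values))
})

test_that("zone labels partition the otolith and exclude background", {
  scan <- tiny_scan(noise = "poisson", seed = 2)
  zl <- scan$truth$zone_label_map
  expect_true(all(zl %in% 0:3))
  expect_true(all(tabulate(zl[zl > 0], 3) > 0))
  # patches stay inside Z2
  ps <- small_preset_scan("patchy_freshwaterZ2", seed = 2)
  expect_true(all(ps$truth$zone_label_map[ps$truth$patch_mask] == 2L))
})

test_that("invalid geometry is rejected with the offending field named", {
  expect_error(tiny_scenario(zone_radii_um = c(35, 10)), "zone_radii_um")
  expect_error(tiny_scenario(zone_radii_um = c(10, 60)), "zone_radii_um")
  expect_error(tiny_scenario(zone_levels_mmolmol = c(-1, 2, 3)),
               "zone_levels_mmolmol")
  expect_error(tiny_scenario(ca_intensity = 0), "ca_intensity")
})

test_that("presets are deterministic and unknown names list the registry", {
  a <- scan_preset("classic_amphidromous", seed = 9)
  b <- scan_preset("classic_amphidromous", seed = 9)
  expect_identical(unclass(a), unclass(b))
  expect_error(scan_preset("nope"), "freshwater_resident")
})

test_that("preset levels respect their documented ranges", {
  for (seed in c(1, 7, 23)) {
    expect_true(all(scan_preset("freshwater_resident", seed)$zone_levels_mmolmol < 4))
    lv <- scan_preset("classic_amphidromous", seed)$zone_levels_mmolmol
    expect_true(lv[1] >= 3 && lv[1] <= 5)
    expect_true(lv[2] >= 6 && lv[2] <= 9)
    expect_true(lv[3] >= 1 && lv[3] <= 2)
  }
  expect_identical(scan_preset("estuarine_hatch", 1)$zone_levels_mmolmol, c(6, 3, 1))
  expect_null(scan_preset("freshwater_resident", 1)$patch_params)
})

test_that("patchy fixture: above-marine area equals the true patch area", {
  # noise-free: pixels above 6 mmol/mol in Z2 are exactly the patch discs
  scan <- small_preset_scan("patchy_freshwaterZ2", seed = 4,
                            noise_model = list(type = "none"))
  zl <- scan$truth$zone_label_map
  ratio <- matrix(0, nrow(zl), ncol(zl))
  ratio[zl > 0] <- scan$sr$values[zl > 0] / scan$ca$values[zl > 0]
  expect_identical(unname(ratio > 6 & zl == 2L), unname(scan$truth$patch_mask))
  # noisy: fraction matches the geometric truth closely
  noisy <- small_preset_scan("patchy_freshwaterZ2", seed = 4)
  zl2 <- noisy$truth$zone_label_map
  r2 <- noisy$sr$values / pmax(noisy$ca$values, 1)
  frac_obs <- sum(r2 > 6 & zl2 == 2L) / sum(zl2 == 2L)
  frac_true <- sum(noisy$truth$patch_mask) / sum(zl2 == 2L)
  expect_lt(abs(frac_obs - frac_true), 0.02)
})

test_that("zone means converge to scenario levels as noise shrinks", {
  lv <- tiny_scenario()$zone_levels_mmolmol
  for (disp in c(4, 1)) {
    sc <- tiny_scenario(noise = "poisson", seed = 5)
    sc$noise_model$dispersion <- disp
    scan <- simulate_scan(sc)
    zl <- scan$truth$zone_label_map
    r <- scan$sr$values / pmax(scan$ca$values, 1)
    for (z in 1:3)
      expect_lt(abs(mean(r[zl == z]) - lv[z]) / lv[z], 0.02)
  }
  # noise-free is exact
  scan0 <- tiny_scan(noise = "none")
  zl0 <- scan0$truth$zone_label_map
  r0 <- scan0$sr$values / pmax(scan0$ca$values, 1)
  for (z in 1:3) expect_equal(mean(r0[zl0 == z]), lv[z], tolerance = 1e-12)
})

test_that("scenario configs round-trip through YAML", {
  sc <- scan_preset("patchy_amphidromous", seed = 3)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, f)
  sc2 <- read_scenario(f)
  expect_equal(unclass(sc), unclass(sc2), tolerance = 1e-12)
  expect_identical(simulate_scan(sc)$sr$values, simulate_scan(sc2)$sr$values)
})
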