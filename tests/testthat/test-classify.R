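test_that("printed-profile evidence reproduces the expected calls", {
  # classic amphidromous pattern
  classic <- classify_evidence(z1_mode = 4, z2_mode = 8, z3_mode = 1.5,
                               z1_max = 4.5, z2_marine_fraction = 0.9)
  expect_identical(classic$category, "amphidromous_classic")
  expect_false(classic$estuarine_hatch)
  # high-salinity hatch, freshwater juvenile phase (torrentius-like profile)
  hatch <- classify_evidence(z2_mode = 3, z3_mode = 0.8, z1_max = 6,
                             z1_mode = 3.5, z2_marine_fraction = 0.0)
  expect_identical(hatch$category, "freshwater_resident")
  expect_true(hatch$estuarine_hatch)
  # heterogeneous Z2 with marine patches (cruentus 8068-like profile)
  patchy <- classify_evidence(z2_mode = 4, z3_mode = 1.5, z1_max = 4,
                              z2_mean = 6, z2_marine_fraction = 0.4)
  expect_identical(patchy$category, "amphidromous_patchy")
  # fully freshwater
  res <- classify_evidence(z2_mode = 2, z3_mode = 2, z1_max = 2,
                           z2_marine_fraction = 0)
  expect_identical(res$category, "freshwater_resident")
  expect_false(res$estuarine_hatch)
})

test_that("missing Z2/Z3 evidence refuses to classify", {
  expect_error(classify_evidence(z2_mode = NA_real_, z3_mode = 1), "required")
  st <- zone_histograms(
    calibrate(compute_ratio_map(element_map(matrix(8, 4, 4), "Sr", 1),
                                element_map(matrix(1, 4, 4), "Ca", 1),
                                matrix(TRUE, 4, 4))),
    zone_map(matrix(1L, 4, 4), 1))
  ps <- detect_patches(
    calibrate(compute_ratio_map(element_map(matrix(8, 4, 4), "Sr", 1),
                                element_map(matrix(1, 4, 4), "Ca", 1),
                                matrix(TRUE, 4, 4))),
    zone_map(matrix(1L, 4, 4), 1))
  expect_error(classify_call(st, ps), "required")
})

test_that("classification is a pure function of evidence and config", {
  args <- list(z2_mode = 5.5, z3_mode = 2, z1_max = 5.2,
               z2_marine_fraction = 0.07)
  a <- do.call(classify_evidence, args)
  b <- do.call(classify_evidence, args)
  expect_identical(a, b)
  expect_identical(a$category, "amphidromous_patchy")
})

test_that("raising marine_lower never turns a resident into a classic call", {
  set.seed(21)
  for (i in 1:200) {
    ev <- list(z2_mode = runif(1, 0, 12), z3_mode = runif(1, 0, 6),
               z1_max = runif(1, 0, 8), z2_marine_fraction = runif(1))
    lo <- do.call(classify_evidence,
                  c(ev, list(config = classifier_config(marine_lower = 6))))
    hi <- do.call(classify_evidence,
                  c(ev, list(config = classifier_config(marine_lower = 8))))
    if (lo$category == "freshwater_resident")
      expect_false(hi$category == "amphidromous_classic")
    # classic under the stricter bound implies classic under the looser one
    if (hi$category == "amphidromous_classic")
      expect_identical(lo$category, "amphidromous_classic")
  }
})

test_that("config invariants are enforced", {
  expect_error(classifier_config(fw_upper = 7), "fw_upper")
  expect_error(classifier_config(estuarine_z1 = 7), "estuarine_z1")
  expect_error(classifier_config(patch_fraction_min = 2), "patch_fraction_min")
})

test_that("cohort batching counts categories and rejects bad input", {
  calls <- list(
    a1 = classify_evidence(z2_mode = 8, z3_mode = 1),
    a2 = classify_evidence(z2_mode = 7, z3_mode = 2),
    p1 = classify_evidence(z2_mode = 3, z3_mode = 1, z2_marine_fraction = 0.3),
    r1 = classify_evidence(z2_mode = 2, z3_mode = 2))
  tab <- classify_batch(calls)
  expect_identical(tab$id, sort(names(calls)))
  cnt <- attr(tab, "counts")
  expect_identical(as.integer(cnt[c("amphidromous_classic", "amphidromous_patchy",
                                    "freshwater_resident")]), c(2L, 1L, 1L))
  expect_error(classify_batch(list()), "at least one")
  dup <- calls[c(1, 1, 2)]
  names(dup) <- c("x", "x", "y")
  expect_error(classify_batch(dup), "duplicate")
})

test_that("a cruentus-like cohort yields exactly three freshwater residents", {
  # one patchy specimen (8068-like) and three residents (8066/8069/8071-like)
  cohort <- list(
    `8068` = classify_evidence(z2_mode = 4, z3_mode = 1.5, z2_mean = 6,
                               z2_marine_fraction = 0.4),
    `8066` = classify_evidence(z2_mode = 3, z3_mode = 1.5,
                               z2_marine_fraction = 0),
    `8069` = classify_evidence(z2_mode = 2.5, z3_mode = 1,
                               z2_marine_fraction = 0.01),
    `8071` = classify_evidence(z2_mode = 3.5, z3_mode = 2,
                               z2_marine_fraction = 0))
  tab <- classify_batch(cohort)
  expect_identical(sum(tab$category == "freshwater_resident"), 3L)
  expect_identical(tab$category[tab$id == "8068"], "amphidromous_patchy")
})
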