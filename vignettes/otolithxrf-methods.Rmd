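---
title: "Methods: Sr:Ca zonation and life-history calls from 2D otolith XRF maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Sr:Ca zonation and life-history calls from 2D otolith XRF maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otolithxrf)
```

## The measurement and the model

Teleost otoliths accrete calcium carbonate continuously and are never
remodelled, so the strontium they trap is a permanent record of the water
the fish lived in: the molar Sr:Ca ratio is conventionally read as
2--4 mmol/mol in freshwater and above 6 mmol/mol in estuarine and marine
water. A synchrotron XRF scan of a sectioned otolith yields two
single-channel intensity rasters (Ca and Sr counts per pixel, typically
0.5 µm pixels). For small amphidromous fish such as freshwater pipefish,
the section shows three concentric zones: Z1, a roughly circular
20--30 µm hatch region around the core; Z2, the juvenile growth zone,
marine (high Sr:Ca) in migratory individuals; and Z3, the adult
freshwater edge zone.

`otolithxrf` turns a Ca/Sr raster pair into a life-history call in five
steps, each exposed as its own function and orchestrated by
`otolith_srca()`:

1. **Masking** (`make_otolith_mask`): the Ca histogram is bimodal
   (resin background vs carbonate); an Otsu split, largest connected
   component, and hole filling give the otolith mask. A constant image
   degrades to a full-frame mask with a warning.
2. **Ratio and calibration** (`compute_ratio_map`, `calibrate`): Sr/Ca
   per pixel on the mask; zero-Ca pixels are removed from the validity
   mask rather than clipped, so division artefacts can never enter a
   histogram. Calibration is a single multiplicative coefficient
   `k` (mmol/mol per unit intensity ratio). Fundamental-parameter
   spectral quantification is out of scope; `k = 1` carries an explicit
   "uncalibrated identity" provenance.
3. **Zonation** (`detect_core`, `extract_transect`,
   `detect_zone_boundaries`, `segment_zones`): described below.
4. **Statistics** (`zone_histograms`, `detect_patches`,
   `granularity_index`): per-zone area-normalised Sr:Ca frequency
   distributions (0.25 mmol/mol bins, 1% reporting threshold),
   8-connected components of Z2 pixels above the marine threshold, and a
   local coefficient-of-variation texture index.
5. **Classification** (`classify_evidence`): explicit threshold rules,
   below.

## Zone segmentation

The default "radial" method assumes zones scale with the local otolith
radius. For each of 8 orientations through the core, both half-transects
are sampled at pixel steps (nearest pixel, then a 2.5 µm moving mean)
and segmented by an exact dynamic-programming piecewise-constant
least-squares fit with three segments. Each half-transect therefore
proposes two boundary radii, expressed as fractions of its own otolith
radius; the consensus is the per-boundary median over all half-transects,
and every pixel is assigned by its fractional radius.

Three qualifications make the consensus robust:

* **Degenerate splits.** When a half-transect has only one real
  transition (e.g. Z1 and Z2 at the same level), the forced third
  segment collapses to a sliver hugging the real step. A middle segment
  narrower than twice the smoothing window is treated as a single
  transition, attributed to the outer boundary when the signal drops
  outward (the return to freshwater is, in this material, always a
  drop), otherwise to the inner one.
* **Patch bumps.** A transect crossing a marine patch fits a narrow,
  high middle segment (prominence > 1.5 mmol/mol on both sides, width
  < 30% of the local radius). Such sides vote for neither boundary.
* **Anatomical Z1 fallback.** If fewer than a quarter of half-transects
  report an inner boundary, the Z1/Z2 transition is chemically
  undefined; Z1 is then the anatomical prior of a 25 µm diameter disc
  at the core (capped at 40% of the Z2 extent), and the boundary is
  flagged unsupported. Classification is unaffected, since the category
  never uses Z1.

The alternative "threshold" method classes pixels by Sr:Ca level
(user-supplied cuts, or an exact exhaustive two-cut Otsu on a 128-bin
histogram of raw values) and then fits the radially ordered three-band
partition that best agrees with those classes, which enforces the
concentric invariant (Z1 contains the core, Z3 touches the edge; radial
distance decides ambiguous pixels). Thresholds are estimated on raw
rather than smoothed values: smoothing manufactures intermediate levels
at zone boundaries that attract a histogram split. A manual label TIFF
(`read_zone_map`) bypasses both methods.

Pixel-level exactness is not attainable even on noise-free synthetic
scans: the analytic zone boundary falls between pixel centres while the
estimated local radius is quantised to the rasterised outline (about
half a pixel). In practice noise-free label accuracy is above 98% and
per-zone Jaccard agreement with ground truth exceeds 0.99 at the default
scan scale; tests assert those bounds rather than identity.

## Classification rules

With `classifier_config()` defaults `fw_upper = 4`, `marine_lower = 6`,
`estuarine_z1 = 5`, `patch_fraction_min = 0.05` (all mmol/mol except the
fraction):

1. *amphidromous_classic*: Z2 mode ≥ 6 and Z3 mode ≤ 4;
2. *amphidromous_patchy*: Z2 mode < 6 but the fraction of Z2 area above
   the marine threshold reaches 0.05, Z3 mode ≤ 4;
3. *freshwater_resident*: Z2 and Z3 modes ≤ 4 and marine fraction
   below 0.05;
4. *indeterminate* otherwise — a classifier over noisy evidence needs an
   abstain state.

Z1 is deliberately excluded from the main category: hatch-zone chemistry
varies independently of the juvenile migration (adults may spawn near
the estuary), and a high-Sr Z1 must not veto a freshwater-resident call.
Z1 only raises the `estuarine_hatch` flag when its maximum reaches
5 mmol/mol in a non-classic individual. The Z2 central tendency is the
binned mode (ties to the lower bin), not the mean: a patchy zone's mean
is pulled by patches that the patch fraction already accounts for. The
5% patch-fraction floor is an invented, configurable threshold — no
published numeric rule exists — chosen so that conspicuous patches count
while single-pixel speckle cannot trigger a migration call.

Monotonicity holds by construction: raising `marine_lower` can only move
calls away from *classic*, never from *resident* to *classic*.

## The synthetic generator

`scan_scenario()`/`simulate_scan()` build a paired Ca/Sr scan with
analytic ground truth: an elliptical otolith (default 140 × 90 µm
semi-axes in a 600 × 400 px, 0.5 µm/px frame), zones as concentric
similar ellipses around the core (outer Z1/Z2 radii 15 and 90 µm along
the major axis), a smooth Ca dome of mean 10⁴ counts (an arbitrary count
scale — beamline publications rarely state per-pixel statistics), Sr
equal to Ca times the zone's Sr:Ca level, and independent per-pixel
Poisson counting noise (photon counting being the physical process),
with a `"none"` option for exact tests. Optional structure: hard
high-Sr discs in Z2 with enforced centre separation (patches), unit-mean
log-normal multiplicative texture in Z1/Z2 (granularity), and a
sinusoidal radial modulation near the Z2/Z3 boundary (rings). The
otolith outline may be offset from the core to exercise core refinement.

Presets encode the observed phenotypes; levels with a documented range
are drawn per seed (classic: Z1 3--5, Z2 6--9, Z3 1--2; resident: all
below 4; estuarine hatch: fixed 6/3/1; a Polynesian variant with patches
up to 16 mmol/mol). The patchy-amphidromous preset uses six discs of
6--12 µm radius so the marine-signature area is on the order of a tenth
of Z2 — conspicuous, as in the phenotype it imitates — while the
`patchy_freshwaterZ2` recovery fixture keeps five smaller discs at a
fixed level 8 on a level-3 background.

What the generator does **not** emulate: irregular otolith outlines and
zone shapes, spatially correlated detector noise, spectral artefacts,
self-absorption, vaterite inclusions, and sub-pixel growth structure.
Green tests therefore demonstrate correctness of the computational
contracts and recoverability under the stated statistical structure, not
performance on real beamline rasters, whose zones are hand-checkable via
the manual-override path.

## Numerical and format choices

* **TIFF**: element maps are written as uncompressed single-channel
  32-bit IEEE-float TIFFs (values are raw counts, far outside the unit
  interval that integer TIFF writers assume) and read back verbatim;
  8/16-bit integer input is accepted with a dynamic-range warning. Zone
  labels use 8-bit TIFFs (0 background, 1--3 zones).
* **Connected components** are labelled by an internal BFS with
  selectable 4/8 connectivity; patches use 8-connectivity, hole filling
  uses the 4-connected complement.
* **Perimeter** for circularity uses the Cauchy--Crofton correction
  (exposed-edge count × π/4), which recovers 2πr on rasterised discs
  where the naive edge count overshoots by 4/π; circularity is clamped
  at its theoretical maximum of 1.
* **Histogram bins** are `[lo, hi)` from zero in 0.25 mmol/mol steps;
  the mode is the centre of the maximal bin with ties going to the lower
  bin, deterministically.
* **Determinism**: one seed controls the generator; the analysis itself
  is seed-free, and a report (JSON, CSVs, label TIFF) regenerates
  byte-identically from the same inputs and configuration. YAML configs
  are written at 17 significant digits so round-trips preserve doubles
  exactly.
* **Display**: rendering is read-only and never feeds back into
  analysis. The LUT is a five-anchor red--yellow--brown--cyan--slate-grey
  gradient (the published palette itself is unavailable, so the anchors
  are an approximation; they are parameterisable), normalised by a
  cohort-wide maximum with background anchored at index 255 so colours
  are comparable across specimens. The 3-3-2 RGB conversion maps the
  three high bits to red, three middle to green, two low to blue
  (the common image-processing convention for this transform), each
  channel rescaled to the full 8-bit range for visibility.
* **Frequency normalisation** is per zone (each zone's raw frequencies
  sum to 1), the reading of "area-normalised" that keeps zones of very
  different sizes comparable in one panel.

## Problem sizes and batch conditions

Unit fixtures run at 160 × 120 px (1 µm pixels, 60 × 40 µm otolith,
zone radii 10/35 µm, levels 3/8/2). Batch work — 50 scans per preset for
category-recovery statistics, plus 25 patch-recovery fixtures — uses
320 × 220 px scans at 1 µm pixels with the default 140 × 90 µm otolith
geometry, a scale at which one full pipeline run takes well under a
second while boundary recovery is still measured at sub-micrometre
error. The single full-resolution demonstration scan uses the default
600 × 400 px at 0.5 µm.

Boundary-recovery error is scored where the generating contrast defines
a boundary: both radii for the classic and estuarine-hatch presets, only
the outer radius for the patchy preset (its Z1 and Z2 levels overlap by
construction), and not at all for the resident preset, whose zones
deliberately share the freshwater range.

## Known limitations

* The radial method assumes zones scale with the local radius; strongly
  eccentric real growth would need the threshold method or a manual
  label map.
* The calibration contract is linear and user-supplied; no attempt is
  made to recover the spectral conversion factor from the rasters.
* Classification thresholds are field conventions, not fitted
  quantities; individuals whose Z2 mode sits at the marine boundary
  (± one bin of 6 mmol/mol) are intrinsically ambiguous between the
  classic and patchy categories, which both read as amphidromous.
* The granularity index quantifies local relative variability only; it
  is not a texture classifier.
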