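Package: otolithxrf
Title: Life-History Reconstruction from 2D Synchrotron-XRF Otolith Sr:Ca Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for paired calcium and strontium X-ray
    fluorescence (XRF) intensity maps of fish otolith sections. Computes
    calibrated pixel-wise Sr:Ca molar-ratio rasters, segments the otolith
    into three concentric growth zones by change-point detection on radial
    transects, summarises per-zone Sr:Ca frequency distributions, detects
    high-Sr marine patches in the juvenile zone, classifies the diadromous
    life history (amphidromous, patchy amphidromous, freshwater resident)
    against configurable salinity-proxy thresholds, and renders the two
    field-standard visualisations (cohort-normalised colour lookup table
    and 3-3-2 RGB bit-slice conversion). Includes a synthetic otolith scan
    generator with analytic ground truth so the full pipeline is testable
    without beamline data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    tiff,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
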