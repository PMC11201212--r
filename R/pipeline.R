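# Per-specimen and cohort orchestration: mask -> ratio -> calibrate ->
# core -> segment -> stats -> patches -> classify -> render, with a
# machine-readable report and a two-pass cohort mode that shares one
# display normalisation across specimens.

#' Default analysis configuration
#'
#' Nested list with one section per pipeline stage; every run resolves
#' and records the configuration it used.
#'
#' @param ... Overrides as `section.key = value` style nested lists, e.g.
#'   `srca_config(classify = list(fw_upper = 3.5))`.
#' @return A list of class `srca_config`.
#' @export
srca_config <- function(...) {
  base <- list(
    calibration = list(k = 1, provenance = "uncalibrated identity"),
    mask = list(method = "otsu", background_quantile = 0.5),
    core = list(method = "centroid", override = NULL),
    zonation = list(method = "radial", n_angles = 8L, smoothing_um = 2.5,
                    n_zones = 3L),
    stats = list(bin_width = 0.25, frequency_threshold = 0.01,
                 marine_threshold = 6, min_patch_area_um2 = 10,
                 granularity_window_um = 5),
    classify = list(fw_upper = 4, marine_lower = 6, estuarine_z1 = 5,
                    patch_fraction_min = 0.05),
    display = list(global_max = NULL, scalebar_um = 50)
  )
  ov <- list(...)
  for (sec in names(ov)) {
    .assert(sec %in% names(base), sprintf("unknown config section '%s'", sec))
    base[[sec]] <- utils::modifyList(base[[sec]], ov[[sec]])
  }
  class(base) <- "srca_config"
  base
}

#' Write / read a resolved configuration
#' @param config An `srca_config`.
#' @param path YAML file path.
#' @return `path` (write) or an `srca_config` (read).
#' @export
write_srca_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 17L)
  invisible(path)
}

#' @rdname write_srca_config
#' @export
read_srca_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(srca_config, raw)
}

#' @noRd
.stage <- function(name, verbose, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(force(expr), error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  if (verbose)
    message(sprintf("  stage %-12s %6.2f s", name, proc.time()[["elapsed"]] - t0))
  out
}

#' Run the full Sr:Ca analysis for one specimen
#'
#' Executes the whole per-specimen workflow on a pair of Ca/Sr element
#' maps: otolith masking, pixel-wise ratio, molar calibration, core
#' location, concentric zone segmentation, per-zone frequency
#' distributions, marine-patch detection, life-history classification
#' and (when `out_dir` is given) rendering and serialisation of the
#' report. Deterministic: the same inputs and configuration reproduce
#' the same report.
#'
#' @param ca,sr [element_map]s, or paths to single-channel TIFFs (then
#'   `pixel_size_um` must be supplied), or an `otolith_scan` passed as
#'   `ca` with `sr` missing.
#' @param config An [srca_config].
#' @param id Specimen identifier used in outputs.
#' @param out_dir Optional output directory: writes `report.json`,
#'   `zones.tif`, `srca_spatialized.csv`, `boundaries.csv`,
#'   `srca_lut.png`, `srca_332.png` and `config.yaml`.
#' @param pixel_size_um Pixel size when `ca`/`sr` are file paths.
#' @param global_max Display normalisation maximum (cohort-wide when
#'   called from [otolith_cohort()]); defaults to the specimen maximum.
#' @param verbose Log one line per stage.
#' @return An object of class `otolith_report`; see
#'   [print.otolith_report()].
#' @examples
#' scan <- simulate_scan(scan_preset("classic_amphidromous", seed = 1,
#'   shape_px = c(120, 160), pixel_size_um = 1.5,
#'   otolith_axes_um = c(110, 75), core_xy_um = c(120, 90)))
#' rep <- otolith_srca(scan, id = "demo")
#' rep$call$category
#' @export
otolith_srca <- function(ca, sr = NULL, config = srca_config(),
                         id = "specimen", out_dir = NULL,
                         pixel_size_um = NULL, global_max = NULL,
                         verbose = FALSE) {
  .assert(inherits(config, "srca_config"), "config must be an srca_config")
  if (inherits(ca, "otolith_scan") && is.null(sr)) {
    sr <- ca$sr; ca <- ca$ca
  }
  ca <- .stage("raster_io", verbose, {
    if (is.character(ca)) {
      .assert(!is.null(pixel_size_um), "pixel_size_um required when reading from file")
      read_element_map(ca, "Ca", pixel_size_um)
    } else ca
  })
  sr <- .stage("raster_io", verbose, {
    if (is.character(sr)) read_element_map(sr, "Sr", pixel_size_um) else sr
  })
  .assert(inherits(ca, "element_map") && inherits(sr, "element_map"),
          "ca and sr must be element_maps or TIFF paths")

  mask <- .stage("mask", verbose,
    make_otolith_mask(ca, config$mask$background_quantile, config$mask$method))
  ratio <- .stage("ratio", verbose, compute_ratio_map(sr, ca, mask))
  ratio <- .stage("calibrate", verbose,
    calibrate(ratio, srca_calibration(config$calibration$k,
                                      config$calibration$provenance)))
  core <- .stage("core", verbose,
    detect_core(ratio, method = config$core$method,
                override = config$core$override))
  zones <- .stage("segment", verbose,
    segment_zones(ratio, core, method = config$zonation$method,
                  n_angles = config$zonation$n_angles,
                  smoothing_um = config$zonation$smoothing_um,
                  n_zones = config$zonation$n_zones))
  stats <- .stage("stats", verbose,
    zone_histograms(ratio, zones, config$stats$bin_width,
                    config$stats$frequency_threshold))
  patches <- .stage("patches", verbose,
    detect_patches(ratio, zones, config$stats$marine_threshold,
                   config$stats$min_patch_area_um2))
  call_ <- .stage("classify", verbose,
    classify_call(stats, patches,
                  classifier_config(config$classify$fw_upper,
                                    config$classify$marine_lower,
                                    config$classify$estuarine_z1,
                                    config$classify$patch_fraction_min)))
  geom <- zone_geometry(zones, core)

  gm <- if (!is.null(global_max)) global_max
        else if (!is.null(config$display$global_max)) config$display$global_max
        else suppressWarnings(max(ratio$values[ratio$valid]))

  report <- structure(list(
    id = id,
    ratio = ratio,
    zones = zones,
    stats = stats,
    patches = patches,
    call = call_,
    geometry = geom,
    core_px = as.numeric(core),
    core_provenance = attr(core, "provenance"),
    global_max = gm,
    config = config,
    provenance = list(config_hash = .object_md5(unclass(config)),
                      package_version = as.character(utils::packageVersion("otolithxrf")))
  ), class = "otolith_report")

  if (!is.null(out_dir)) .stage("render", verbose, write_report(report, out_dir))
  report
}

#' Write an otolith report's artefacts to a directory
#'
#' Emits the machine-readable `report.json` (content-deterministic: no
#' timestamps), the zone label TIFF, the spatialized CSV, the per-angle
#' boundary CSV (radial method), both PNG renderings and the resolved
#' config.
#'
#' @param report An [otolith_srca()] report.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  .assert(inherits(report, "otolith_report"), "report must be an otolith_report")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_zone_map(report$zones, p("zones.tif"))
  export_spatialized_csv(report$ratio, report$zones, p("srca_spatialized.csv"))
  if (!is.null(report$zones$boundaries$per_angle))
    utils::write.csv(report$zones$boundaries$per_angle, p("boundaries.csv"),
                     row.names = FALSE)
  render_map_png(report$ratio, p("srca_lut.png"), global_max = report$global_max,
                 mode = "lut", scalebar_um = report$config$display$scalebar_um)
  render_map_png(report$ratio, p("srca_332.png"), global_max = report$global_max,
                 mode = "332")
  write_srca_config(report$config, p("config.yaml"))
  json <- list(
    id = report$id,
    category = report$call$category,
    estuarine_hatch = report$call$estuarine_hatch,
    evidence = report$call$evidence,
    zone_summaries = zone_summaries(report$stats),
    zone_geometry = report$geometry,
    patches = report$patches$patches,
    z2_marine_fraction = report$patches$z2_marine_fraction,
    core_px = report$core_px,
    core_provenance = report$core_provenance,
    boundaries = report$zones$boundaries[c("f1", "f2")],
    global_max = report$global_max,
    provenance = report$provenance
  )
  jsonlite::write_json(json, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(out_dir)
}

#' @export
print.otolith_report <- function(x, ...) {
  cat(sprintf("<otolith_report> %s\n", x$id))
  print(x$call)
  cat(sprintf("  core (x, z) = (%.1f, %.1f) px [%s]; zones: %s\n",
              x$core_px[1], x$core_px[2], x$core_provenance,
              x$zones$provenance))
  invisible(x)
}

#' @export
summary.otolith_report <- function(object, ...) {
  cat(sprintf("Specimen %s - %s%s\n", object$id, object$call$category,
              if (object$call$estuarine_hatch) " (estuarine hatch)" else ""))
  cat("\nZone summaries (Sr:Ca mmol/mol):\n")
  print(zone_summaries(object$stats), row.names = FALSE)
  cat("\nZone geometry:\n")
  print(object$geometry, row.names = FALSE)
  cat(sprintf("\nPatches > %g mmol/mol: %d (Z2 marine fraction %.3f)\n",
              object$patches$marine_threshold_mmolmol,
              nrow(object$patches$patches),
              object$patches$z2_marine_fraction))
  invisible(object)
}

#' Plot an otolith report
#'
#' Three panels: the LUT-rendered Sr:Ca map, a horizontal transect
#' through the core, and the per-zone frequency distributions.
#'
#' @param x An [otolith_srca()] report.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.otolith_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  idx <- normalize_for_display(x$ratio, x$global_max)
  rgb <- apply_lut(idx, srca_lut(x$global_max))
  graphics::plot(NA, xlim = c(0, ncol(idx)), ylim = c(nrow(idx), 0),
                 asp = 1, xlab = "x (px)", ylab = "z (px)", main = x$id)
  graphics::rasterImage(rgb, 0, nrow(idx), ncol(idx), 0)
  tr <- extract_transect(x$ratio, x$core_px, 0,
                         x$config$zonation$smoothing_um)
  plot(tr, main = "transect through core")
  plot(x$stats, main = "per-zone Sr:Ca frequencies")
  invisible(x)
}

#' Run the pipeline over a cohort with shared display normalisation
#'
#' Two passes over the manifest: the first computes every specimen's
#' Sr:Ca maximum and takes the cohort-wide maximum; the second analyses
#' and renders every specimen against that shared scale, so colours are
#' comparable between specimens. Classification never sees the display
#' normalisation.
#'
#' @param manifest Either a `data.frame` with columns `id`, `ca_path`,
#'   `sr_path` or a named list of `otolith_scan` objects.
#' @param config An [srca_config].
#' @param out_dir Optional directory; per-specimen subdirectories plus
#'   `cohort.csv` are written there.
#' @param pixel_size_um Pixel size for file-based manifests.
#' @param verbose Log stages.
#' @return List of class `otolith_cohort`: `reports` (named list),
#'   `table` (the [classify_batch()] cohort table), `global_max`.
#' @export
otolith_cohort <- function(manifest, config = srca_config(), out_dir = NULL,
                           pixel_size_um = NULL, verbose = FALSE) {
  if (is.data.frame(manifest)) {
    .assert(all(c("id", "ca_path", "sr_path") %in% names(manifest)),
            "manifest needs columns id, ca_path, sr_path")
    .assert(nrow(manifest) >= 1, "manifest lists no specimens")
    if (anyDuplicated(manifest$id))
      stop(sprintf("duplicate specimen IDs in manifest: %s",
                   paste(unique(manifest$id[duplicated(manifest$id)]), collapse = ", ")),
           call. = FALSE)
    missing <- c(manifest$ca_path[!file.exists(manifest$ca_path)],
                 manifest$sr_path[!file.exists(manifest$sr_path)])
    if (length(missing))
      stop(sprintf("missing input files: %s", paste(missing, collapse = ", ")),
           call. = FALSE)
    .assert(!is.null(pixel_size_um), "pixel_size_um required for file manifests")
    loaders <- lapply(seq_len(nrow(manifest)), function(i) {
      function() list(ca = read_element_map(manifest$ca_path[i], "Ca", pixel_size_um),
                      sr = read_element_map(manifest$sr_path[i], "Sr", pixel_size_um))
    })
    ids <- manifest$id
  } else {
    .assert(is.list(manifest) && length(manifest) >= 1 &&
              all(vapply(manifest, inherits, TRUE, "otolith_scan")),
            "manifest must be a data.frame or a named list of otolith_scans")
    ids <- names(manifest)
    .assert(!is.null(ids) && all(nzchar(ids)), "scan list must be named by specimen ID")
    if (anyDuplicated(ids))
      stop("duplicate specimen IDs in scan list", call. = FALSE)
    loaders <- lapply(manifest, function(s) function() list(ca = s$ca, sr = s$sr))
  }
  k <- config$calibration$k
  # pass 1: streaming cohort maximum of the calibrated ratio
  global_max <- 0
  for (ld in loaders) {
    maps <- ld()
    mask <- make_otolith_mask(maps$ca, config$mask$background_quantile,
                              config$mask$method)
    r <- compute_ratio_map(maps$sr, maps$ca, mask)
    m <- suppressWarnings(max(r$values[r$valid]))
    if (is.finite(m)) global_max <- max(global_max, m * k)
  }
  # pass 2: full analysis against the shared scale
  reports <- list()
  for (i in seq_along(loaders)) {
    maps <- loaders[[i]]()
    sub <- if (is.null(out_dir)) NULL else file.path(out_dir, ids[i])
    reports[[ids[i]]] <- otolith_srca(maps$ca, maps$sr, config = config,
                                      id = ids[i], out_dir = sub,
                                      global_max = global_max,
                                      verbose = verbose)
  }
  tab <- classify_batch(reports)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  }
  structure(list(reports = reports, table = tab, global_max = global_max),
            class = "otolith_cohort")
}

#' @export
print.otolith_cohort <- function(x, ...) {
  cat(sprintf("<otolith_cohort> %d specimens, shared display max %.3g mmol/mol\n",
              length(x$reports), x$global_max))
  print(x$table, row.names = FALSE)
  cat("\ncategory counts:\n")
  print(attr(x$table, "counts"))
  invisible(x)
}
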