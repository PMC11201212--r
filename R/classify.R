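# Threshold-based diadromy classification: turns per-zone Sr:Ca
# summaries and the Z2 marine-patch fraction into a categorical
# life-history call.

#' Classifier thresholds
#'
#' Salinity-proxy bounds used by [classify_evidence()]. Defaults follow
#' the conventional otolith Sr:Ca reading: 2--4 mmol/mol in freshwater,
#' above 6 in estuarine/sea water, with Z1 values above 5 flagging a
#' high-salinity (estuarine) hatching environment. `patch_fraction_min`
#' is the smallest Z2 marine-area fraction accepted as evidence of a
#' marine passage; no published numeric rule exists for it, so it is an
#' explicit, configurable choice (default 0.05).
#'
#' @param fw_upper Freshwater upper bound on a zone mode (default 4).
#' @param marine_lower Marine lower bound on the Z2 mode (default 6).
#' @param estuarine_z1 Z1 max threshold for the estuarine-hatch flag
#'   (default 5).
#' @param patch_fraction_min Minimum `z2_marine_fraction` to call a
#'   marine passage from patches alone (default 0.05).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(fw_upper = 4, marine_lower = 6,
                              estuarine_z1 = 5, patch_fraction_min = 0.05) {
  .assert(fw_upper > 0 && fw_upper <= estuarine_z1 && estuarine_z1 <= marine_lower,
          "thresholds must satisfy 0 < fw_upper <= estuarine_z1 <= marine_lower")
  .assert(patch_fraction_min >= 0 && patch_fraction_min <= 1,
          "patch_fraction_min must be in [0, 1]")
  structure(list(fw_upper = fw_upper, marine_lower = marine_lower,
                 estuarine_z1 = estuarine_z1,
                 patch_fraction_min = patch_fraction_min),
            class = "classifier_config")
}

#' Classify a life history from explicit evidence values
#'
#' Pure decision function (identical evidence and config always give the
#' identical call). Rules, applied in order:
#' \enumerate{
#'   \item `amphidromous_classic` if the Z2 mode is at least
#'     `marine_lower` and the Z3 mode at most `fw_upper`;
#'   \item `amphidromous_patchy` if the Z2 mode is below `marine_lower`
#'     but the Z2 marine-area fraction reaches `patch_fraction_min` and
#'     the Z3 mode is at most `fw_upper`;
#'   \item `freshwater_resident` if Z2 and Z3 modes are both at most
#'     `fw_upper` and the marine fraction stays below
#'     `patch_fraction_min`;
#'   \item `indeterminate` otherwise.
#' }
#' The main category deliberately ignores Z1 (hatching signatures vary
#' independently of the juvenile migration); Z1 only sets the
#' `estuarine_hatch` flag, raised when the Z1 maximum reaches
#' `estuarine_z1` while the category is not already classic.
#'
#' @param z2_mode,z3_mode Zone modal Sr:Ca (mmol/mol); both required.
#' @param z1_max Z1 maximum Sr:Ca (mmol/mol), `NA` allowed.
#' @param z2_marine_fraction Fraction of Z2 area above the marine
#'   threshold; `NA` treated as 0.
#' @param z1_mode,z2_mean Optional context carried into the evidence.
#' @param config A [classifier_config].
#' @return An object of class `life_history_call`: `category`,
#'   `estuarine_hatch`, `evidence`, `config`.
#' @examples
#' classify_evidence(z2_mode = 8, z3_mode = 1.5, z1_max = 4,
#'                   z2_marine_fraction = 0.9)$category
#' @export
classify_evidence <- function(z2_mode, z3_mode, z1_max = NA_real_,
                              z2_marine_fraction = 0,
                              z1_mode = NA_real_, z2_mean = NA_real_,
                              config = classifier_config()) {
  .assert(inherits(config, "classifier_config"), "config must be a classifier_config")
  if (!is.finite(z2_mode) || !is.finite(z3_mode))
    stop("cannot classify: Z2 and Z3 summaries are required", call. = FALSE)
  frac <- if (is.finite(z2_marine_fraction)) z2_marine_fraction else 0
  category <- if (z2_mode >= config$marine_lower && z3_mode <= config$fw_upper) {
    "amphidromous_classic"
  } else if (z2_mode < config$marine_lower && frac >= config$patch_fraction_min &&
             z3_mode <= config$fw_upper) {
    "amphidromous_patchy"
  } else if (z2_mode <= config$fw_upper && z3_mode <= config$fw_upper &&
             frac < config$patch_fraction_min) {
    "freshwater_resident"
  } else {
    "indeterminate"
  }
  estuarine <- isTRUE(is.finite(z1_max) && z1_max >= config$estuarine_z1 &&
                        category != "amphidromous_classic")
  structure(list(category = category,
                 estuarine_hatch = estuarine,
                 evidence = list(z1_mode = z1_mode, z1_max = z1_max,
                                 z2_mode = z2_mode, z2_mean = z2_mean,
                                 z3_mode = z3_mode,
                                 z2_marine_fraction = frac),
                 config = config),
            class = "life_history_call")
}

#' Classify a specimen from its zone statistics and patch set
#'
#' Convenience wrapper extracting the evidence from [zone_histograms()]
#' and [detect_patches()] outputs and delegating to
#' [classify_evidence()].
#'
#' @param stats A [zone_stats][zone_histograms].
#' @param patches A [patch_set][detect_patches].
#' @param config A [classifier_config].
#' @return A `life_history_call`.
#' @export
classify_call <- function(stats, patches, config = classifier_config()) {
  .assert(inherits(stats, "zone_stats"), "stats must be a zone_stats")
  .assert(inherits(patches, "patch_set"), "patches must be a patch_set")
  s <- stats$zones
  classify_evidence(z2_mode = s$Z2$mode, z3_mode = s$Z3$mode,
                    z1_max = s$Z1$max, z1_mode = s$Z1$mode,
                    z2_mean = s$Z2$mean,
                    z2_marine_fraction = patches$z2_marine_fraction,
                    config = config)
}

#' @export
print.life_history_call <- function(x, ...) {
  ev <- x$evidence
  cat(sprintf("<life_history_call> %s%s\n", x$category,
              if (x$estuarine_hatch) " (estuarine hatch)" else ""))
  cat(sprintf("  Z1 mode %.2f max %.2f | Z2 mode %.2f mean %.2f | Z3 mode %.2f | Z2 marine fraction %.3f\n",
              ev$z1_mode, ev$z1_max, ev$z2_mode, ev$z2_mean, ev$z3_mode,
              ev$z2_marine_fraction))
  invisible(x)
}

#' Classify a cohort of specimen reports
#'
#' @param reports Named list: specimen ID to either a `life_history_call`
#'   or an `otolith_report` (from [otolith_srca()]).
#' @return `data.frame` ordered by ID with columns `id`, `category`,
#'   `estuarine_hatch`, `z2_mode`, `z3_mode`, `z2_marine_fraction`;
#'   category counts attached as attribute `"counts"`.
#' @export
classify_batch <- function(reports) {
  .assert(length(reports) >= 1, "classify_batch needs at least one report")
  ids <- names(reports)
  .assert(!is.null(ids) && all(nzchar(ids)), "reports must be a named list of specimen IDs")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate specimen IDs: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  calls <- lapply(reports, function(r) {
    if (inherits(r, "otolith_report")) r$call
    else if (inherits(r, "life_history_call")) r
    else stop("each report must be a life_history_call or otolith_report", call. = FALSE)
  })
  tab <- do.call(rbind, lapply(seq_along(calls), function(i) {
    cl <- calls[[i]]
    data.frame(id = ids[i], category = cl$category,
               estuarine_hatch = cl$estuarine_hatch,
               z2_mode = cl$evidence$z2_mode, z3_mode = cl$evidence$z3_mode,
               z2_marine_fraction = cl$evidence$z2_marine_fraction)
  }))
  tab <- tab[order(tab$id), , drop = FALSE]
  rownames(tab) <- NULL
  counts <- table(factor(tab$category,
                         levels = c("amphidromous_classic", "amphidromous_patchy",
                                    "freshwater_resident", "indeterminate")))
  attr(tab, "counts") <- counts
  tab
}
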