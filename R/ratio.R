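# Sr:Ca ratio computation and calibration: otolith masking from the Ca
# map, pixel-wise division with degenerate-pixel masking, and the linear
# intensity-ratio -> molar-ratio calibration.

#' Estimate the otolith mask from the Ca map
#'
#' The Ca intensity distribution of a scan is bimodal (empty resin
#' background vs carbonate); the mask takes pixels above an automatic
#' Otsu split, falling back to the stated intensity quantile when the
#' split is degenerate, then keeps the largest connected component and
#' fills interior holes.
#'
#' @param ca Ca [element_map].
#' @param background_quantile Fallback threshold quantile (default 0.5),
#'   used only when the Otsu split fails.
#' @param method `"otsu"` (default) or `"quantile"`.
#' @return Logical matrix, `TRUE` on otolith pixels. A unimodal image
#'   (no separable background) returns a full-frame mask with a warning.
#' @export
make_otolith_mask <- function(ca, background_quantile = 0.5,
                              method = c("otsu", "quantile")) {
  .assert(inherits(ca, "element_map"), "ca must be an element_map")
  method <- match.arg(method)
  v <- ca$values
  if (stats::sd(v) == 0 || diff(range(v)) < 1e-12 * max(abs(v), 1)) {
    warning("Ca image is constant: no background separable, using full-frame mask",
            call. = FALSE)
    return(matrix(TRUE, nrow(v), ncol(v)))
  }
  thr <- if (method == "otsu") .otsu(as.numeric(v)) else NA_real_
  if (!is.finite(thr)) thr <- stats::quantile(v, background_quantile)
  mask <- v > thr
  # degenerate split: essentially everything on one side
  frac <- mean(mask)
  if (frac < 0.001 || frac > 0.999) {
    warning("Ca intensity distribution looks unimodal; using full-frame mask",
            call. = FALSE)
    return(matrix(TRUE, nrow(v), ncol(v)))
  }
  .fill_holes(.largest_component(mask, connectivity = 8))
}

#' @noRd
new_ratio_map <- function(values, valid, calibrated, pixel_size_um,
                          provenance = "computed") {
  structure(list(values = values, valid = valid, calibrated = calibrated,
                 pixel_size_um = pixel_size_um, provenance = provenance,
                 unit = if (calibrated) "mmol/mol" else "intensity ratio"),
            class = "ratio_map")
}

#' Pixel-wise Sr:Ca ratio raster
#'
#' Divides the Sr by the Ca map pixel by pixel on the otolith mask.
#' Pixels where Ca is zero are removed from the validity mask rather than
#' producing infinities, so division artefacts can never leak into
#' downstream histograms. The result is an uncalibrated intensity ratio;
#' see [calibrate()].
#'
#' @param sr,ca Sr and Ca [element_map]s with identical shape and pixel
#'   size, from the same acquisition.
#' @param mask Logical otolith mask (e.g. from [make_otolith_mask()]).
#' @return A `ratio_map`: list with `values` (ratio, 0 outside validity),
#'   `valid` (logical), `calibrated = FALSE`, `pixel_size_um`.
#' @examples
#' ca <- element_map(matrix(100, 4, 4), "Ca", 0.5)
#' sr <- element_map(matrix(200, 4, 4), "Sr", 0.5)
#' r <- compute_ratio_map(sr, ca, matrix(TRUE, 4, 4))
#' unique(as.vector(r$values))
#' @export
compute_ratio_map <- function(sr, ca, mask) {
  .assert(inherits(sr, "element_map") && inherits(ca, "element_map"),
          "sr and ca must be element_maps")
  if (!all(dim(sr$values) == dim(ca$values)))
    stop("Sr and Ca maps have different shapes", call. = FALSE)
  if (sr$pixel_size_um != ca$pixel_size_um)
    stop("Sr and Ca maps have different pixel sizes", call. = FALSE)
  .assert(is.logical(mask) && all(dim(mask) == dim(ca$values)),
          "mask must be a logical matrix congruent with the maps")
  valid <- mask & ca$values > 0
  vals <- matrix(0, nrow(ca$values), ncol(ca$values))
  vals[valid] <- sr$values[valid] / ca$values[valid]
  new_ratio_map(vals, valid, calibrated = FALSE,
                pixel_size_um = ca$pixel_size_um)
}

#' @export
print.ratio_map <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf("<ratio_map> %dx%d px, %d valid, %s [%s], range [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values), sum(x$valid),
              if (x$calibrated) "calibrated" else "uncalibrated",
              x$unit, if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Linear Sr:Ca calibration model
#'
#' A single multiplicative coefficient `k` converting the XRF intensity
#' ratio to a molar Sr:Ca ratio in mmol/mol. Full fundamental-parameter
#' spectral quantification is out of scope here; `k` is expected from an
#' upstream spectral fit, and the default `k = 1` identity carries an
#' explicit "uncalibrated identity" provenance so its use is auditable.
#'
#' @param k Positive coefficient (mmol/mol per unit intensity ratio).
#' @param provenance Free-text origin of the coefficient.
#' @return An object of class `srca_calibration`.
#' @export
srca_calibration <- function(k = 1, provenance = "uncalibrated identity") {
  .assert(is.numeric(k) && length(k) == 1 && is.finite(k) && k > 0,
          "calibration coefficient k must be a single positive number")
  structure(list(k = as.numeric(k), provenance = provenance),
            class = "srca_calibration")
}

#' Calibrate an intensity-ratio map to molar Sr:Ca
#'
#' Multiplies every valid ratio by the calibration coefficient and marks
#' the map as calibrated (unit mmol/mol). Calibrating twice is an error.
#'
#' @param ratio An uncalibrated [ratio_map][compute_ratio_map].
#' @param model An [srca_calibration].
#' @return The calibrated `ratio_map`.
#' @export
calibrate <- function(ratio, model = srca_calibration()) {
  .assert(inherits(ratio, "ratio_map"), "ratio must be a ratio_map")
  .assert(inherits(model, "srca_calibration"), "model must be an srca_calibration")
  if (ratio$calibrated)
    stop("ratio map is already calibrated; double calibration refused", call. = FALSE)
  out <- ratio
  out$values <- ratio$values * model$k
  out$calibrated <- TRUE
  out$unit <- "mmol/mol"
  out$provenance <- model$provenance
  out
}
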