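# Zonation: core location, radial transects, change-point boundary
# detection and allocation of every otolith pixel to the three concentric
# growth zones Z1 (hatch), Z2 (juvenile) and Z3 (adult).

#' @noRd
new_zone_map <- function(labels, pixel_size_um, provenance = "auto",
                         boundaries = NULL) {
  structure(list(labels = labels, pixel_size_um = pixel_size_um,
                 provenance = provenance, boundaries = boundaries),
            class = "zone_map")
}

#' Construct a zone label map from an explicit label matrix
#'
#' Escape hatch for manually drawn segmentations (see also
#' [read_zone_map()]): wraps an integer matrix of labels (0 =
#' background, 1..3 = Z1..Z3) as a `zone_map` usable by every
#' downstream operation.
#'
#' @param labels Integer matrix with values in 0..3.
#' @param pixel_size_um Pixel size in micrometres.
#' @param provenance Label origin (default `"manual-override"`).
#' @return A `zone_map`.
#' @export
zone_map <- function(labels, pixel_size_um, provenance = "manual-override") {
  .assert(is.matrix(labels) && all(labels %in% 0:3),
          "labels must be an integer matrix with values in 0..3")
  storage.mode(labels) <- "integer"
  new_zone_map(labels, pixel_size_um, provenance = provenance)
}

#' @export
print.zone_map <- function(x, ...) {
  tab <- tabulate(x$labels[x$labels > 0L], 3L)
  cat(sprintf("<zone_map> %dx%d px, Z1 %d | Z2 %d | Z3 %d px (%s)\n",
              nrow(x$labels), ncol(x$labels), tab[1], tab[2], tab[3],
              x$provenance))
  invisible(x)
}

#' Locate the otolith core
#'
#' The default estimate is the centroid of the otolith mask. With
#' `method = "refine"` the estimate is sharpened by looking for the most
#' central compact region whose Sr:Ca level departs from its local
#' surroundings (the Z1 candidate): within a central disc the smoothed
#' ratio is split by an Otsu threshold and the centroid of the most
#' central minority component is returned, falling back to the mask
#' centroid when no convincing candidate exists. An explicit
#' `override = c(x, z)` (0-based pixel coordinates) is returned verbatim
#' with provenance `"manual-override"`.
#'
#' @param ratio A calibrated [ratio_map][compute_ratio_map] with a
#'   non-empty validity mask.
#' @param method `"centroid"` (default) or `"refine"`.
#' @param override Optional `c(x, z)` manual core position in pixels.
#' @return Numeric `c(x, z)` 0-based pixel coordinates with a
#'   `"provenance"` attribute.
#' @export
detect_core <- function(ratio, method = c("centroid", "refine"),
                        override = NULL) {
  .assert(inherits(ratio, "ratio_map"), "ratio must be a ratio_map")
  if (!is.null(override)) {
    .assert(length(override) == 2, "override must be c(x, z)")
    return(structure(as.numeric(override), provenance = "manual-override"))
  }
  method <- match.arg(method)
  if (!any(ratio$valid)) stop("empty otolith mask: cannot locate core", call. = FALSE)
  idx <- which(ratio$valid)
  nr <- nrow(ratio$values)
  cx <- mean((idx - 1L) %/% nr)
  cz <- mean((idx - 1L) %% nr)
  centroid <- c(cx, cz)
  if (method == "centroid")
    return(structure(centroid, provenance = "auto"))
  pf <- .polar_frame(ratio$valid, centroid, ratio$pixel_size_um)
  central <- ratio$valid & pf$r_um < 0.4 * stats::median(pf$edge_um)
  sm <- .box_sums(ifelse(ratio$valid, ratio$values, NA_real_), 5L)
  smoothed <- sm$sum / pmax(sm$n, 1L)
  v <- smoothed[central]
  thr <- .otsu(v)
  if (!is.finite(thr)) return(structure(centroid, provenance = "auto"))
  hi <- smoothed > thr
  minority <- if (mean(hi[central]) <= 0.5) hi else !hi
  cand <- minority & central
  lab <- .label_components(cand, connectivity = 8)
  if (max(lab) == 0L) return(structure(centroid, provenance = "auto"))
  sizes <- tabulate(lab[lab > 0L])
  best <- NULL; best_d <- Inf
  for (k in which(sizes >= 10L)) {
    ki <- which(lab == k)
    kx <- mean((ki - 1L) %/% nr); kz <- mean((ki - 1L) %% nr)
    d <- sqrt((kx - cx)^2 + (kz - cz)^2)
    if (d < best_d) { best_d <- d; best <- c(kx, kz) }
  }
  if (is.null(best)) return(structure(centroid, provenance = "auto"))
  structure(best, provenance = "auto-refined")
}

#' Extract an edge-to-edge Sr:Ca transect through the core
#'
#' Samples the ratio map along the full chord through the core at
#' pixel-size steps using nearest-pixel lookup, then applies an NA-aware
#' moving-average of the stated physical width. Masked gaps are carried
#' as missing values.
#'
#' @param ratio A calibrated [ratio_map][compute_ratio_map].
#' @param core `c(x, z)` core position in 0-based pixels.
#' @param angle_deg Chord orientation in degrees (0 = +x axis, measured
#'   towards +z).
#' @param smoothing_um Moving-average window width in micrometres; `0`
#'   returns raw nearest-pixel values.
#' @return An object of class `radial_transect`: `positions_um` (strictly
#'   increasing along the chord, 0 at the first valid sample), `srca`,
#'   `core_position_um`, `angle_deg`, `pixel_size_um`.
#' @export
extract_transect <- function(ratio, core, angle_deg, smoothing_um = 2.5) {
  .assert(inherits(ratio, "ratio_map"), "ratio must be a ratio_map")
  px <- ratio$pixel_size_um
  nr <- nrow(ratio$values); nc <- ncol(ratio$values)
  cr <- round(core[2]) + 1L; ccol <- round(core[1]) + 1L
  .assert(cr >= 1 && cr <= nr && ccol >= 1 && ccol <= nc, "core outside the raster")
  if (!ratio$valid[cr, ccol])
    stop("core does not lie inside the otolith mask", call. = FALSE)
  th <- angle_deg * pi / 180
  dx <- cos(th); dz <- sin(th)
  kmax <- ceiling(sqrt(nr^2 + nc^2))
  k <- (-kmax):kmax
  xs <- core[1] + k * dx
  zs <- core[2] + k * dz
  inb <- xs >= -0.5 & xs <= nc - 0.5 & zs >= -0.5 & zs <= nr - 0.5
  k <- k[inb]; xs <- xs[inb]; zs <- zs[inb]
  ri <- pmin(pmax(round(zs) + 1L, 1L), nr)
  ci <- pmin(pmax(round(xs) + 1L, 1L), nc)
  pidx <- (ci - 1L) * nr + ri
  vals <- ifelse(ratio$valid[pidx], ratio$values[pidx], NA_real_)
  ok <- which(!is.na(vals))
  if (length(ok) < 10)
    stop("transect has fewer than 10 valid samples at this angle", call. = FALSE)
  lo <- min(ok); hi <- max(ok)
  k <- k[lo:hi]; vals <- vals[lo:hi]
  if (smoothing_um > 0) {
    w <- max(1L, round(smoothing_um / px))
    if (w %% 2 == 0) w <- w + 1L
    if (w > 1) {
      n <- length(vals)
      sm <- vals
      for (i in seq_len(n)) {
        j <- max(1L, i - (w - 1L) %/% 2L):min(n, i + (w - 1L) %/% 2L)
        v <- vals[j]
        sm[i] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      }
      vals <- sm
    }
  }
  structure(list(positions_um = (k - k[1]) * px,
                 srca = vals,
                 core_position_um = (0 - k[1]) * px,
                 angle_deg = angle_deg,
                 pixel_size_um = px),
            class = "radial_transect")
}

# Exact dynamic-programming piecewise-constant least-squares segmentation:
# y split into k contiguous segments minimising total within-segment SSE.
# Returns the last index of segments 1..k-1 (the change points).
#' @noRd
.pcw_segment <- function(y, k) {
  n <- length(y)
  .assert(n >= k, "fewer samples than segments")
  s1 <- c(0, cumsum(y))
  s2 <- c(0, cumsum(y^2))
  # cost of segment i..j, vectorized over i for fixed j
  cost_to <- function(j) {
    i <- seq_len(j)
    len <- j - i + 1
    (s2[j + 1] - s2[i]) - (s1[j + 1] - s1[i])^2 / len
  }
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)
  for (j in seq_len(n)) D[1, j] <- cost_to(j)[1]
  if (k > 1) {
    for (s in 2:k) {
      for (j in s:n) {
        cj <- cost_to(j)
        cand <- D[s - 1, (s - 1):(j - 1)] + cj[s:j]
        m <- which.min(cand)
        D[s, j] <- cand[m]
        B[s, j] <- (s:j)[m]   # start index of segment s
      }
    }
  }
  bp <- integer(0)
  j <- n
  if (k > 1) for (s in k:2) {
    st <- B[s, j]
    bp <- c(st - 1L, bp)
    j <- st - 1L
  }
  bp
}

#' Detect zone boundaries on a radial transect
#'
#' Fits an exact piecewise-constant least-squares model with `n_zones`
#' segments to each half of the transect (core to edge) and reports the
#' change-point radii. Transitions between zones appear as steep slopes
#' in the Sr:Ca profile; the segment breaks land on them.
#'
#' @param transect A [radial_transect][extract_transect].
#' @param n_zones Number of concentric zones (default 3).
#' @return List with `left` and `right`: increasing boundary radii in
#'   micrometres from the core, `n_zones - 1` per side.
#' @export
detect_zone_boundaries <- function(transect, n_zones = 3L) {
  .assert(inherits(transect, "radial_transect"), "transect must be a radial_transect")
  .assert(n_zones >= 2, "n_zones must be at least 2")
  pos <- transect$positions_um
  y <- transect$srca
  cp <- transect$core_position_um
  one_side <- function(p, v) {
    ok <- !is.na(v)
    p <- p[ok]; v <- v[ok]
    if (length(v) < 3 * n_zones)
      stop("too few valid samples on one side of the core", call. = FALSE)
    if (stats::sd(v) < 1e-10 * max(mean(abs(v)), 1e-12) || stats::sd(v) == 0)
      stop("transect side is constant: no admissible segmentation; supply manual thresholds",
           call. = FALSE)
    bp <- .pcw_segment(v, n_zones)
    lo <- c(1L, bp + 1L); hi <- c(bp, length(v))
    list(radii = sort((p[bp] + p[bp + 1L]) / 2),
         seg_len = hi - lo + 1L,
         seg_means = vapply(seq_along(lo),
                            function(i) mean(v[lo[i]:hi[i]]), 0))
  }
  left_sel <- pos <= cp
  right_sel <- pos >= cp
  left <- one_side(rev(cp - pos[left_sel]), rev(y[left_sel]))
  right <- one_side(pos[right_sel] - cp, y[right_sel])
  structure(list(left = left$radii, right = right$radii),
            details = list(left = left, right = right))
}

#' Allocate otolith pixels to the three concentric zones
#'
#' Two methods. `"radial"` (default): zone boundaries are detected
#' independently on each half-transect over `n_angles` orientations
#' through the core, expressed as fractions of the local otolith radius,
#' and combined by their median; zones are then concentric bands whose
#' extent scales with the local radius in every direction. `"threshold"`:
#' pixels are first classed by intensity thresholds (supplied, or fitted
#' automatically) on the smoothed map, then relabelled into the radially
#' ordered bands that best agree with those classes, which enforces the
#' concentric ordering invariant (Z1 contains the core, Z3 touches the
#' edge; radial distance decides ambiguous pixels).
#'
#' @param ratio A calibrated [ratio_map][compute_ratio_map].
#' @param core `c(x, z)` core pixel position (see [detect_core()]).
#' @param method `"radial"` or `"threshold"`.
#' @param n_angles Number of transect orientations for the radial
#'   consensus (each contributes two half-transects; default 8).
#' @param smoothing_um Transect / map smoothing width in micrometres.
#' @param n_zones Number of zones (default 3).
#' @param thresholds Optional increasing numeric thresholds
#'   (`n_zones - 1` values, mmol/mol) for the threshold method.
#' @return A `zone_map`: integer `labels` (0 background, 1..3 = Z1..Z3),
#'   `pixel_size_um`, `provenance`, and `boundaries` (consensus
#'   fractional radii plus the per-angle table for the radial method).
#' @export
segment_zones <- function(ratio, core, method = c("radial", "threshold"),
                          n_angles = 8L, smoothing_um = 2.5, n_zones = 3L,
                          thresholds = NULL) {
  .assert(inherits(ratio, "ratio_map"), "ratio must be a ratio_map")
  method <- match.arg(method)
  px <- ratio$pixel_size_um
  pf <- .polar_frame(ratio$valid, core, px)
  frac <- ratio$pixel_size_um * 0 + pf$r_um / pf$edge_um[pf$bin]

  if (method == "radial") {
    angles <- seq(0, 180, length.out = n_angles + 1L)[seq_len(n_angles)]
    # shortest admissible middle segment: a boundary pair closer than this
    # is one real transition caught twice by the forced segment count
    min_mid <- max(3, round(2 * smoothing_um / px))
    rows <- list()
    for (ang in angles) {
      res <- tryCatch({
        tr <- extract_transect(ratio, core, ang, smoothing_um)
        bd <- detect_zone_boundaries(tr, n_zones)
        det <- attr(bd, "details")
        pos <- tr$positions_um
        ok <- !is.na(tr$srca)
        Rs <- c(left = tr$core_position_um - min(pos[ok]),
                right = max(pos[ok]) - tr$core_position_um)
        lapply(c("left", "right"), function(side) {
          d <- det[[side]]
          r1 <- d$radii[1]; r2 <- d$radii[n_zones - 1L]
          if (n_zones == 3L) {
            mid_w <- r2 - r1
            m <- d$seg_means
            if (m[2] > m[1] + 1.5 && m[2] > m[3] + 1.5 &&
                mid_w < 0.3 * Rs[[side]]) {
              # narrow high bump: the fit latched onto a marine patch,
              # not onto zonal structure; this side casts no vote
              r1 <- NA_real_; r2 <- NA_real_
            } else if (d$seg_len[2] < min_mid) {
              # degenerate split: a single real transition; attribute it
              # to the outer (return-to-freshwater) boundary when the
              # signal drops outward, to the inner one otherwise
              r <- mean(c(r1, r2))
              if (m[3] < m[1]) { r1 <- NA_real_; r2 <- r }
              else { r1 <- r; r2 <- NA_real_ }
            }
          }
          data.frame(angle_deg = ang, side = side, r1_um = r1, r2_um = r2,
                     R_um = Rs[[side]])
        })
      }, error = function(e) NULL)
      if (!is.null(res)) rows <- c(rows, res)
    }
    if (length(rows) < n_angles)
      stop("radial segmentation failed on most transects; supply manual thresholds",
           call. = FALSE)
    tab <- do.call(rbind, rows)
    n_sides <- 2L * n_angles
    if (sum(!is.na(tab$r2_um)) < max(4, n_sides / 4))
      stop("too few transects show an outer zone transition; supply manual thresholds",
           call. = FALSE)
    f2 <- stats::median(tab$r2_um / tab$R_um, na.rm = TRUE)
    f1_supported <- sum(!is.na(tab$r1_um)) >= n_sides / 4
    if (f1_supported) {
      f1 <- stats::median(tab$r1_um / tab$R_um, na.rm = TRUE)
      r1_abs_um <- NA_real_
    } else {
      # no detectable Z1/Z2 transition (levels too close): fall back to
      # the anatomical prior of a ~25 um diameter hatch zone at the core
      r1_abs_um <- min(12.5, 0.4 * f2 * stats::median(pf$edge_um))
      f1 <- NA_real_
    }
    bounds <- list(f1 = f1, f2 = f2, f1_supported = f1_supported,
                   r1_abs_um = r1_abs_um, per_angle = tab)
  } else {
    if (is.null(thresholds)) {
      thresholds <- .otsu_multi(ratio$values[ratio$valid], n_classes = n_zones)
      if (any(!is.finite(thresholds)))
        stop("map too homogeneous for automatic thresholds; supply them explicitly",
             call. = FALSE)
    }
    .assert(length(thresholds) == n_zones - 1L,
            "thresholds must have n_zones - 1 values")
    # raw values for class assignment: the radial band fit aggregates, so
    # per-pixel speckle is harmless, while smoothing would smear the
    # boundary pixels asymmetrically
    cls <- matrix(0L, nrow(ratio$values), ncol(ratio$values))
    cls[ratio$valid] <- 1L + findInterval(ratio$values[ratio$valid], sort(thresholds))
    # order intensity classes by mean fractional radius -> radial ranks
    mean_f <- sapply(1:n_zones, function(k) mean(frac[cls == k]))
    rank_of <- rank(mean_f, ties.method = "first")
    rk <- matrix(0L, nrow(cls), ncol(cls))
    rk[ratio$valid] <- rank_of[cls[ratio$valid]]
    # best radial band boundaries (agreement with the intensity classes)
    nb <- 200L
    fb <- pmin(frac, 1)
    bin <- pmin(nb, 1L + floor(fb * nb))
    cnt <- sapply(1:n_zones, function(r)
      tabulate(bin[ratio$valid & rk == r], nb))
    C <- apply(cnt, 2, cumsum)
    best <- c(-Inf, 1L, 2L)
    pre <- C[, 1] - C[, 2]
    pre_max <- cummax(pre); pre_arg <- seq_len(nb)
    for (i in 2:nb) if (pre[i] < pre_max[i]) pre_arg[i] <- pre_arg[i - 1L]
    for (b2 in 2:(nb - 1L)) {
      sc <- pre_max[b2 - 1L] + (C[b2, 2] - C[b2, 3]) + C[nb, 3]
      if (sc > best[1]) best <- c(sc, pre_arg[b2 - 1L], b2)
    }
    f1 <- best[2] / nb; f2 <- best[3] / nb
    bounds <- list(f1 = f1, f2 = f2, f1_supported = TRUE,
                   thresholds = thresholds)
  }

  labels <- matrix(0L, nrow(ratio$values), ncol(ratio$values))
  labels[ratio$valid] <- 3L
  labels[ratio$valid & frac <= bounds$f2] <- 2L
  if (is.finite(bounds$f1)) {
    labels[ratio$valid & frac <= bounds$f1] <- 1L
  } else {
    labels[ratio$valid & pf$r_um <= bounds$r1_abs_um] <- 1L
  }
  zm <- new_zone_map(labels, px, provenance = paste0("auto-", method),
                     boundaries = bounds)
  .check_zone_invariants(zm, ratio, core)
  zm
}

# Partition and concentric-ordering invariants, checked after every
# segmentation. On violation the label map is dumped for diagnosis.
#' @noRd
.check_zone_invariants <- function(zones, ratio, core) {
  ok_part <- identical(unname(zones$labels > 0L), unname(ratio$valid))
  nr <- nrow(zones$labels)
  mean_r <- sapply(1:3, function(z) {
    i <- which(zones$labels == z)
    if (!length(i)) return(NA_real_)
    mean(sqrt(((i - 1L) %/% nr - core[1])^2 + ((i - 1L) %% nr - core[2])^2))
  })
  ok_ord <- all(is.finite(mean_r)) && all(diff(mean_r) > 0)
  if (!ok_part || !ok_ord) {
    dump <- tempfile("zone_diagnostic_", fileext = ".tif")
    tiff::writeTIFF(zones$labels / 255, dump, bits.per.sample = 8L)
    stop(sprintf("zone segmentation violated %s invariant; diagnostic map dumped to %s",
                 if (!ok_part) "the partition" else "the concentric-ordering",
                 dump), call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-zone geometry: area, equivalent diameter, circularity
#'
#' Area is pixel count times pixel area; equivalent diameter is
#' `2 * sqrt(area / pi)`; circularity is `4 * pi * area / perimeter^2`
#' with the perimeter estimated from the exposed-edge count under the
#' Cauchy--Crofton correction (factor pi / 4), which is unbiased for
#' smooth convex outlines such as the near-circular Z1.
#'
#' @param zones A `zone_map`.
#' @param core Unused placeholder for API symmetry, may be `NULL`.
#' @return `data.frame` with one row per zone: `zone`, `area_px`,
#'   `area_um2`, `equiv_diameter_um`, `circularity`. Empty zones report
#'   zero area and missing diameter/circularity.
#' @export
zone_geometry <- function(zones, core = NULL) {
  .assert(inherits(zones, "zone_map"), "zones must be a zone_map")
  px <- zones$pixel_size_um
  out <- lapply(1:3, function(z) {
    m <- zones$labels == z
    apx <- sum(m)
    if (apx == 0L)
      return(data.frame(zone = paste0("Z", z), area_px = 0L, area_um2 = 0,
                        equiv_diameter_um = NA_real_, circularity = NA_real_))
    a_um2 <- apx * px^2
    edges <- sum(m & !rbind(FALSE, m[-nrow(m), ])) +
      sum(m & !rbind(m[-1, ], FALSE)) +
      sum(m & !cbind(FALSE, m[, -ncol(m)])) +
      sum(m & !cbind(m[, -1], FALSE))
    per_um <- edges * px * pi / 4
    # clamp at 1: edge-count perimeter estimates on pixelated near-circular
    # shapes can undershoot slightly, and circularity is <= 1 by definition
    data.frame(zone = paste0("Z", z), area_px = apx, area_um2 = a_um2,
               equiv_diameter_um = 2 * sqrt(a_um2 / pi),
               circularity = pmin(1, 4 * pi * a_um2 / per_um^2))
  })
  do.call(rbind, out)
}
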