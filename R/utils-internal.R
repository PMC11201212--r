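# Internal raster primitives shared across modules. All matrices are
# row = z (down), col = x (right); coordinates are 0-based pixel indices
# so that (x, z) printed in CSV matches the documented convention.

#' @noRd
.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Connected-component labelling by breadth-first flood fill.
# connectivity 4 or 8. Returns integer matrix, 0 = background,
# components numbered 1..k in first-encounter (row-major) order.
#' @noRd
.label_components <- function(mask, connectivity = 8) {
  .assert(connectivity %in% c(4, 8), "connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  if (connectivity == 4) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  }
  k <- 0L
  queue <- integer(length(idx))
  for (start in idx) {
    if (lab[start] != 0L) next
    k <- k + 1L
    lab[start] <- k
    queue[1L] <- start
    head <- 1L; tail <- 1L
    while (head <= tail) {
      p <- queue[head]; head <- head + 1L
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (d in seq_along(dr)) {
        r2 <- r + dr[d]; c2 <- cc + dc[d]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        q <- (c2 - 1L) * nr + r2
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- k
          tail <- tail + 1L
          if (tail > length(queue)) queue <- c(queue, integer(length(queue)))
          queue[tail] <- q
        }
      }
    }
  }
  lab
}

#' @noRd
.largest_component <- function(mask, connectivity = 8) {
  lab <- .label_components(mask, connectivity)
  if (max(lab) <= 1L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# Fill holes: background components (4-connected complement) not touching
# the image border are interior holes.
#' @noRd
.fill_holes <- function(mask) {
  lab <- .label_components(!mask, connectivity = 4)
  if (max(lab) == 0L) return(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  mask | (lab > 0L & !(lab %in% border))
}

# Box-filter sums over a w x w window (w odd) via integral image, with
# NA-aware counting: returns list(sum, n) of in-window totals of finite
# values and their counts.
#' @noRd
.box_sums <- function(values, w) {
  .assert(w %% 2 == 1 && w >= 1, "window must be odd and >= 1")
  v <- values
  ok <- is.finite(v)
  v[!ok] <- 0
  nr <- nrow(v); nc <- ncol(v)
  pad <- (w - 1L) / 2L
  csum <- function(m) {
    m2 <- rbind(0, apply(m, 2, cumsum))
    t(rbind(0, apply(t(m2), 2, cumsum)))
  }
  I <- csum(v); N <- csum(ok + 0)
  r1 <- pmax(seq_len(nr) - pad, 1L); r2 <- pmin(seq_len(nr) + pad, nr)
  c1 <- pmax(seq_len(nc) - pad, 1L); c2 <- pmin(seq_len(nc) + pad, nc)
  win <- function(M) {
    M[r2 + 1L, c2 + 1L, drop = FALSE] - M[r1, c2 + 1L, drop = FALSE] -
      M[r2 + 1L, c1, drop = FALSE] + M[r1, c1, drop = FALSE]
  }
  list(sum = win(I), n = win(N))
}

# Separable Gaussian blur with reflecting edges; sigma in pixels.
#' @noRd
.gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_reflect <- function(x, h) c(x[h:1], x, x[length(x):(length(x) - h + 1L)])
  conv1 <- function(x) {
    xp <- pad_reflect(x, half)
    stats::filter(xp, k, sides = 2)[(half + 1L):(half + length(x))]
  }
  m1 <- apply(m, 2, conv1)
  t(apply(t(m1), 2, conv1))
}

# Otsu threshold on a numeric vector (256-bin histogram between range).
#' @noRd
.otsu <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(NA_real_)
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins)), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  rng[1] + k / nbins * diff(rng)
}

# Exact multi-class Otsu: exhaustive search over n_classes - 1 cut points
# of a 128-bin histogram, maximising between-class variance. Deterministic.
# Only n_classes = 2 or 3 are needed here.
#' @noRd
.otsu_multi <- function(x, n_classes = 3L, nbins = 128L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rep(NA_real_, n_classes - 1L))
  b <- pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins))
  h <- tabulate(b, nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  W <- c(0, cumsum(p))
  M <- c(0, cumsum(p * mids))
  cls_term <- function(i, j) { # between-class contribution of bins (i, j]
    w <- W[j + 1L] - W[i + 1L]
    ifelse(w > 0, (M[j + 1L] - M[i + 1L])^2 / w, 0)
  }
  if (n_classes == 2L) {
    crit <- sapply(1:(nbins - 1L), function(t) cls_term(0L, t) + cls_term(t, nbins))
    t1 <- which.max(crit)
    return((mids[t1] + mids[t1 + 1L]) / 2)
  }
  best <- c(-Inf, NA, NA)
  for (t1 in 1:(nbins - 2L)) {
    a <- cls_term(0L, t1)
    t2 <- (t1 + 1L):(nbins - 1L)
    crit <- a + cls_term(t1, t2) + cls_term(t2, nbins)
    m <- which.max(crit)
    if (crit[m] > best[1]) best <- c(crit[m], t1, t2[m])
  }
  c((mids[best[2]] + mids[best[2] + 1L]) / 2,
    (mids[best[3]] + mids[best[3] + 1L]) / 2)
}

# MD5 of a serialized R object (stable given identical content).
#' @noRd
.object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # version = 2 for stability across R sessions of the same major line
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

# Per-pixel polar coordinates around a core given in 0-based (x, z) pixels.
# Returns radius (um), angle bin index (1..nbins), and the per-bin otolith
# edge radius R(theta) (um) smoothed circularly over +-1 bin.
#' @noRd
.polar_frame <- function(mask, core_px, pixel_size_um, nbins = 360L) {
  nr <- nrow(mask); nc <- ncol(mask)
  x <- matrix(rep(0:(nc - 1L), each = nr), nr, nc) - core_px[1]
  z <- matrix(rep(0:(nr - 1L), times = nc), nr, nc) - core_px[2]
  r_um <- sqrt(x^2 + z^2) * pixel_size_um
  ang <- atan2(z, x)                    # (-pi, pi]
  bin <- 1L + ((floor((ang + pi) / (2 * pi) * nbins)) %% nbins)
  edge <- rep(0, nbins)
  inb <- which(mask)
  agg <- tapply(r_um[inb], bin[inb], max)
  # + half a pixel: the outermost pixel centre sits inside the true edge
  edge[as.integer(names(agg))] <- agg + 0.5 * pixel_size_um
  # circular smoothing (mean over bin-1, bin, bin+1), ignoring empty bins
  prev <- edge[c(nbins, 1:(nbins - 1L))]
  nxt <- edge[c(2:nbins, 1L)]
  m <- cbind(prev, edge, nxt)
  w <- m > 0
  sm <- rowSums(m * w) / pmax(rowSums(w), 1)
  edge <- ifelse(sm > 0, sm, max(edge))
  list(r_um = r_um, bin = bin, edge_um = edge)
}
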