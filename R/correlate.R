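# Correlative AFM/SSRM identification: remove the periodic lattice from the
# height map, find low-conductivity sites in the current map, find
# exosome-like bumps in the lattice-free residual, and classify each site by
# the joint decision table.  Coordinates are nm from the map origin
# (top-left); matrix rows run along y, columns along x.

#' AFM height map / SSRM current map containers
#'
#' Thin wrappers around a numeric matrix carrying the pixel size.  Heights
#' are in nm; currents are normalized (arbitrary units).
#'
#' @param mat numeric matrix, all values finite.  Rows index y (row 1 at the
#'   top), columns index x.
#' @param pixel_size pixel size in nm (> 0).
#' @return object of class `height_map` / `current_map` (and `surface_map`).
#' @export
height_map <- function(mat, pixel_size) {
  new_surface_map(mat, pixel_size, "height_map")
}

#' @rdname height_map
#' @export
current_map <- function(mat, pixel_size) {
  new_surface_map(mat, pixel_size, "current_map")
}

new_surface_map <- function(mat, pixel_size, cls) {
  stopifnot(is.matrix(mat), is.numeric(mat), pixel_size > 0)
  if (any(!is.finite(mat))) stop("map values must all be finite.")
  structure(mat, pixel_size = pixel_size, class = c(cls, "surface_map"))
}

#' @export
print.surface_map <- function(x, ...) {
  px <- attr(x, "pixel_size")
  cat(sprintf("%s: %d x %d px, %.3g nm/px (%.2f x %.2f um)\n",
              class(x)[1], nrow(x), ncol(x), px,
              nrow(x) * px / 1000, ncol(x) * px / 1000))
  cat(sprintf("  range: %.3g to %.3g\n", min(x), max(x)))
  invisible(x)
}

#' @export
plot.surface_map <- function(x, ...) {
  px <- attr(x, "pixel_size")
  graphics::image(x = (seq_len(ncol(x)) - 0.5) * px,
                  y = (seq_len(nrow(x)) - 0.5) * px,
                  z = t(unclass(x))[, rev(seq_len(nrow(x)))],
                  xlab = "x (nm)", ylab = "y (nm)", useRaster = TRUE, ...)
}

#' Remove the periodic lattice from a height map
#'
#' Fourier notch filter for the doubly modulated lattice.  A lattice that is
#' (additively) separable along the two scan axes has all of its spectral
#' energy -- the fundamental at `1/L`, its harmonics, and the leakage that
#' arises whenever the period does not divide the scan size -- on the two
#' frequency axes `(fx, 0)` and `(0, fy)`.  The default notch therefore
#' suppresses those axis lines entirely (plus the mean), which removes the
#' lattice and any global tilt while costing a bump only the vanishing
#' fraction `~2/N` of its energy.  Passing `harmonics` switches to narrow
#' notches of `notch_bins` bins at the first `harmonics` multiples of `1/L`,
#' appropriate when the period divides the scan size exactly.
#'
#' @param hmap a [height_map()].
#' @param L lattice period in nm; must exceed twice the pixel size.
#' @param harmonics `NULL` (default) to notch the full frequency axes, or
#'   the number of harmonics to notch narrowly.
#' @param notch_bins width of each narrow notch in frequency bins
#'   (default 3; odd).
#' @return a [height_map()] holding the lattice-free residual (offset-free).
#' @export
remove_lattice <- function(hmap, L, harmonics = NULL, notch_bins = 3) {
  stopifnot(inherits(hmap, "height_map"))
  px <- attr(hmap, "pixel_size")
  if (L <= 2 * px) stop("lattice period L is not resolvable by the grid ",
                        "(need L > 2 * pixel_size).")
  m <- unclass(hmap) - mean(hmap)
  n <- nrow(m); k <- ncol(m)
  fm <- stats::fft(m)
  wrap <- function(idx, len) ((idx - 1) %% len) + 1
  if (is.null(harmonics)) {
    fm[1, ] <- 0   # all modulation along x (plus residual row means)
    fm[, 1] <- 0   # all modulation along y
  } else {
    half <- (notch_bins - 1) %/% 2
    for (j in seq_len(harmonics)) {
      b_row <- round(j * n * px / L)   # bin index along rows (y frequency)
      b_col <- round(j * k * px / L)
      rows <- wrap(c(1 + b_row + (-half:half), 1 - b_row + (-half:half)), n)
      cols <- wrap(c(1 + b_col + (-half:half), 1 - b_col + (-half:half)), k)
      fm[rows, 1] <- 0   # modulation along y
      fm[1, cols] <- 0   # modulation along x
    }
  }
  res <- Re(stats::fft(fm, inverse = TRUE)) / (n * k)
  height_map(res, px)
}

# connected-component labelling with centroids (nm) and region stats
label_regions <- function(mask, pixel_size) {
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab == 0) {
    return(data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      area_px = integer(0), radius = numeric(0)))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  lb <- lab[lab > 0]
  cy <- tapply((idx[, 1] - 0.5) * pixel_size, lb, mean)
  cx <- tapply((idx[, 2] - 0.5) * pixel_size, lb, mean)
  area <- tabulate(lb, nbins = nlab)
  data.frame(label = seq_len(nlab), x = as.numeric(cx), y = as.numeric(cy),
             area_px = area,
             radius = sqrt(area / pi) * pixel_size)
}

#' Detect low-conductivity sites in an SSRM current map
#'
#' Connected regions where the current falls below
#' `(1 - drop_fraction) * median(current)`, reported with centroid (nm) and
#' equivalent radius.
#'
#' @param cmap a [current_map()].
#' @param drop_fraction fractional drop defining "significant" (default 0.9,
#'   i.e. current below 10% of the median).
#' @param min_area_px discard regions smaller than this many pixels
#'   (default 4; suppresses single-pixel noise).
#' @return data frame with `x`, `y`, `radius` (nm) and `area_px`.
#' @export
detect_low_conductivity <- function(cmap, drop_fraction = 0.9,
                                    min_area_px = 4) {
  stopifnot(inherits(cmap, "current_map"), drop_fraction > 0,
            drop_fraction < 1)
  thr <- (1 - drop_fraction) * stats::median(cmap)
  mask <- unclass(cmap) < thr
  sites <- label_regions(mask, attr(cmap, "pixel_size"))
  sites[sites$area_px >= min_area_px, , drop = FALSE]
}

#' Detect exosome-like bumps in a lattice-free height residual
#'
#' Thresholds the residual at `min_height`, labels connected blobs, and for
#' each blob reports the peak height, the lateral full width at half maximum
#' (equivalent diameter of the area above half the peak), and a cluster flag
#' (more than one well-separated local maximum).  Blobs whose FWHM falls
#' outside `size_gate` are rejected.
#'
#' @param residual a [height_map()] from [remove_lattice()].
#' @param min_height detection threshold in nm (default 25, about six times
#'   the default synthetic roughness rms; bumps from vesicles smaller than
#'   ~55 nm fall below it at the default cap ratio).
#' @param size_gate accepted lateral FWHM range in nm (default `c(30, 150)`,
#'   the typical exosome diameter range).
#' @param min_area_px discard blobs smaller than this many pixels.
#' @return data frame with `x`, `y` (nm), `height` (nm), `fwhm` (nm),
#'   `cluster` (logical).
#' @export
detect_bumps <- function(residual, min_height = 25, size_gate = c(30, 150),
                         min_area_px = 4) {
  stopifnot(inherits(residual, "height_map"), min_height > 0)
  px <- attr(residual, "pixel_size")
  m <- unclass(residual)
  mask <- m > min_height
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  out <- data.frame(x = numeric(0), y = numeric(0), height = numeric(0),
                    fwhm = numeric(0), cluster = logical(0))
  if (nlab == 0) return(out)
  for (l in seq_len(nlab)) {
    sel <- which(lab == l, arr.ind = TRUE)
    if (nrow(sel) < min_area_px) next
    vals <- m[sel]
    peak <- max(vals)
    ipk <- sel[which.max(vals), ]
    # FWHM: area above half the peak, connected to this blob's peak
    half_mask <- m > peak / 2
    hlab <- EBImage::bwlabel(half_mask)
    area_half <- sum(hlab == hlab[ipk[1], ipk[2]])
    fwhm <- 2 * sqrt(area_half / pi) * px
    # cluster: several local maxima above 60% of peak, > 2 px apart
    loc <- sel[vals > 0.6 * peak, , drop = FALSE]
    n_max <- 0L
    if (nrow(loc) > 0) {
      vv <- m[loc]
      ord <- order(vv, decreasing = TRUE)
      kept <- matrix(numeric(0), ncol = 2)
      for (i in ord) {
        p <- loc[i, , drop = FALSE]
        if (!is_local_max(m, p[1], p[2])) next
        if (nrow(kept) == 0 ||
            all(sqrt((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2) > 3)) {
          kept <- rbind(kept, p)
        }
      }
      n_max <- nrow(kept)
    }
    if (fwhm < size_gate[1] || fwhm > size_gate[2]) next
    out <- rbind(out, data.frame(
      x = (ipk[2] - 0.5) * px, y = (ipk[1] - 0.5) * px,
      height = peak, fwhm = fwhm, cluster = n_max > 1))
  }
  rownames(out) <- NULL
  out
}

is_local_max <- function(m, i, j) {
  ni <- max(1, i - 1):min(nrow(m), i + 1)
  nj <- max(1, j - 1):min(ncol(m), j + 1)
  m[i, j] >= max(m[ni, nj])
}

#' Classify co-registered SSRM/AFM sites
#'
#' Joint decision table of the correlative procedure: a low-conductivity site
#' coinciding (within `match_radius`) with an exosome-like bump is an
#' `exosome`; a low-conductivity site with no topographic feature is a
#' `silver_defect` (missing metal); a bump with normal conductivity is an
#' `imperfection` (polymer bump formed before metal deposition).  The
#' classification is invariant to a global height offset and to global
#' current scaling, since both detectors are.
#'
#' @param ssrm_sites data frame from [detect_low_conductivity()].
#' @param afm_sites data frame from [detect_bumps()].
#' @param match_radius maximum centre distance for pairing, nm (default 200,
#'   one half-period: objects settle in depression centres).
#' @return data frame (`site_table`): `x`, `y` (nm), `low_conductivity`,
#'   `bump` (logicals), `lateral_size`, `bump_height` (nm, `NA` without a
#'   bump), `cluster`, `class`.
#' @export
classify_sites <- function(ssrm_sites, afm_sites, match_radius = 200) {
  stopifnot(is.data.frame(ssrm_sites), is.data.frame(afm_sites))
  used_afm <- rep(FALSE, nrow(afm_sites))
  rows <- list()
  for (i in seq_len(nrow(ssrm_sites))) {
    s <- ssrm_sites[i, ]
    j <- NA_integer_
    if (nrow(afm_sites) > 0) {
      d <- sqrt((afm_sites$x - s$x)^2 + (afm_sites$y - s$y)^2)
      d[used_afm] <- Inf
      if (min(d) <= match_radius) j <- which.min(d)
    }
    if (!is.na(j)) {
      used_afm[j] <- TRUE
      b <- afm_sites[j, ]
      rows[[length(rows) + 1]] <- data.frame(
        x = b$x, y = b$y, low_conductivity = TRUE, bump = TRUE,
        lateral_size = b$fwhm, bump_height = b$height,
        cluster = b$cluster, class = "exosome")
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        x = s$x, y = s$y, low_conductivity = TRUE, bump = FALSE,
        lateral_size = 2 * s$radius, bump_height = NA_real_,
        cluster = FALSE, class = "silver_defect")
    }
  }
  for (j in which(!used_afm)) {
    b <- afm_sites[j, ]
    rows[[length(rows) + 1]] <- data.frame(
      x = b$x, y = b$y, low_conductivity = FALSE, bump = TRUE,
      lateral_size = b$fwhm, bump_height = b$height,
      cluster = b$cluster, class = "imperfection")
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else {
    data.frame(x = numeric(0), y = numeric(0),
               low_conductivity = logical(0), bump = logical(0),
               lateral_size = numeric(0), bump_height = numeric(0),
               cluster = logical(0), class = character(0))
  }
  class(out) <- c("site_table", "data.frame")
  out
}

#' Score a site table against generator ground truth
#'
#' Matches classified sites to planted objects by position and reports
#' per-class precision and recall.
#'
#' @param sites a site table from [classify_sites()].
#' @param truth ground-truth table from [gen_surface_pair()].
#' @param match_radius maximum centre distance in nm.
#' @return data frame with `class`, `n_truth`, `n_called`, `tp`, `precision`,
#'   `recall`.
#' @export
score_classification <- function(sites, truth, match_radius = 200) {
  classes <- c("exosome", "silver_defect", "imperfection")
  rows <- lapply(classes, function(cl) {
    tr <- truth[truth$class == cl, , drop = FALSE]
    ca <- sites[sites$class == cl, , drop = FALSE]
    used <- rep(FALSE, nrow(ca))
    tp <- 0L
    for (i in seq_len(nrow(tr))) {
      if (nrow(ca) == 0) break
      d <- sqrt((ca$x - tr$x[i])^2 + (ca$y - tr$y[i])^2)
      d[used] <- Inf
      if (length(d) > 0 && min(d) <= match_radius) {
        used[which.min(d)] <- TRUE
        tp <- tp + 1L
      }
    }
    data.frame(class = cl, n_truth = nrow(tr), n_called = nrow(ca), tp = tp,
               precision = if (nrow(ca) > 0) tp / nrow(ca) else NA_real_,
               recall = if (nrow(tr) > 0) tp / nrow(tr) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Height profile along a polyline with modulation statistics
#'
#' Interpolates the height map bilinearly along a polyline and summarises the
#' lattice modulation as the peak-to-valley swings between consecutive local
#' extrema of the profile.
#'
#' Crests and troughs are located on a lightly smoothed copy of the profile
#' (so pixel-scale roughness does not masquerade as lattice extrema) and then
#' refined to the raw extremum within the smoothing window.
#'
#' @param hmap a [height_map()].
#' @param polyline two-column matrix of vertices `(x, y)` in nm; must lie
#'   inside the map.
#' @param step sampling step along the line in nm (default half a pixel).
#' @param smooth_sigma Gaussian smoothing scale in nm used for extremum
#'   detection (default 30; set to 0 to use the raw profile).
#' @return list with `distance` (nm along the line), `height` (nm), `swings`
#'   (per-half-period peak-to-valley values), `mean_modulation`,
#'   `min_modulation`, `max_modulation`.
#' @export
cross_section <- function(hmap, polyline,
                          step = attr(hmap, "pixel_size") / 2,
                          smooth_sigma = 30) {
  stopifnot(inherits(hmap, "height_map"), is.matrix(polyline),
            ncol(polyline) == 2, nrow(polyline) >= 2)
  px <- attr(hmap, "pixel_size")
  extent_x <- ncol(hmap) * px; extent_y <- nrow(hmap) * px
  if (any(polyline[, 1] < 0) || any(polyline[, 1] > extent_x) ||
      any(polyline[, 2] < 0) || any(polyline[, 2] > extent_y)) {
    stop("polyline lies (partly) outside the map.")
  }
  pts <- list(); dist0 <- 0; dists <- c(); xs <- c(); ys <- c()
  for (s in seq_len(nrow(polyline) - 1)) {
    p0 <- polyline[s, ]; p1 <- polyline[s + 1, ]
    len <- sqrt(sum((p1 - p0)^2))
    tt <- seq(0, len, by = step)
    xs <- c(xs, p0[1] + (p1[1] - p0[1]) * tt / len)
    ys <- c(ys, p0[2] + (p1[2] - p0[2]) * tt / len)
    dists <- c(dists, dist0 + tt)
    dist0 <- dist0 + len
  }
  hh <- bilinear_at(hmap, xs, ys)
  # locate lattice extrema on a smoothed profile, refine on the raw one
  sm <- hh
  if (smooth_sigma > 0 && length(hh) > 5) {
    ks <- smooth_sigma / step
    kk <- stats::dnorm(seq(-ceiling(3 * ks), ceiling(3 * ks)), sd = ks)
    kk <- kk / sum(kk)
    sm <- stats::filter(hh, kk, sides = 2)
    pad <- which(is.na(sm))
    sm[pad] <- hh[pad]
    sm <- as.numeric(sm)
  }
  ext_idx <- which(diff(sign(diff(sm))) != 0) + 1
  win <- max(1L, ceiling(smooth_sigma / step))
  ext <- vapply(ext_idx, function(i) {
    lo <- max(1L, i - win); hi <- min(length(hh), i + win)
    if (sm[i] >= sm[i - 1] && sm[i] >= sm[i + 1]) max(hh[lo:hi])
    else min(hh[lo:hi])
  }, numeric(1))
  swings <- abs(diff(ext))
  swings <- swings[swings > 0.05 * (max(hh) - min(hh))]  # ignore micro-ripples
  list(distance = dists, height = hh, swings = swings,
       mean_modulation = if (length(swings)) mean(swings) else 0,
       min_modulation = if (length(swings)) min(swings) else 0,
       max_modulation = if (length(swings)) max(swings) else 0)
}

bilinear_at <- function(map, x, y) {
  px <- attr(map, "pixel_size")
  m <- unclass(map)
  # pixel centres at (j - 0.5) px; clamp to the centre lattice
  fx <- pmin(pmax(x / px - 0.5, 0), ncol(m) - 1)
  fy <- pmin(pmax(y / px - 0.5, 0), nrow(m) - 1)
  j0 <- pmin(floor(fx) + 1, ncol(m) - 1); i0 <- pmin(floor(fy) + 1, nrow(m) - 1)
  tx <- fx - (j0 - 1); ty <- fy - (i0 - 1)
  m[cbind(i0, j0)] * (1 - tx) * (1 - ty) +
    m[cbind(i0, j0 + 1)] * tx * (1 - ty) +
    m[cbind(i0 + 1, j0)] * (1 - tx) * ty +
    m[cbind(i0 + 1, j0 + 1)] * tx * ty
}

#' Estimate the lattice period of a height map
#'
#' Averages the one-dimensional power spectrum over all rows (x direction)
#' and over all columns (y direction) and converts the dominant non-zero
#' spatial frequency to a period in nm.  Fails when no frequency dominates
#' (e.g. white noise).
#'
#' @param hmap a [height_map()] spanning at least four lattice periods.
#' @param min_contrast required ratio of the dominant peak to the median
#'   spectral power (default 10).
#' @return estimated period in nm.
#' @export
estimate_period <- function(hmap, min_contrast = 10) {
  stopifnot(inherits(hmap, "height_map"))
  px <- attr(hmap, "pixel_size")
  m <- unclass(hmap)
  spec_1d <- function(mm) {
    # mean power spectrum of the rows of mm
    mm <- mm - rowMeans(mm)
    p <- Mod(stats::mvfft(t(mm)))^2  # columns = transformed rows
    rowMeans(p)
  }
  n <- ncol(m)
  p <- spec_1d(m) + spec_1d(t(m))
  half <- p[2:(floor(n / 2))]
  k <- which.max(half)           # cycles per map width
  if (max(half) < min_contrast * stats::median(half)) {
    stop("no dominant spatial frequency: cannot estimate a lattice period.")
  }
  n * px / k
}
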