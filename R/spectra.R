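# SERS spectrum processing: baseline, noise, band intensity, S/N-based limit
# of detection, peak detection and band assignment.  Wavenumbers are Raman
# (Stokes) shifts in cm^-1; the pipeline default span is 600-1700 cm^-1.

#' Construct a Raman spectrum
#'
#' @param shift wavenumber axis in cm^-1, strictly increasing.
#' @param intensity intensities (counts), same length, all finite.
#' @param label optional character label.
#' @param concentration optional analyte concentration in uM.
#' @param seed optional integer recording the generator seed.
#' @return object of class `raman_spectrum` (list with `shift`, `intensity`
#'   and metadata fields).
#' @export
raman_spectrum <- function(shift, intensity, label = NULL,
                           concentration = NULL, seed = NULL) {
  shift <- as.numeric(shift); intensity <- as.numeric(intensity)
  if (length(shift) != length(intensity)) {
    stop("shift and intensity must have the same length.")
  }
  if (length(shift) < 2 || any(diff(shift) <= 0)) {
    stop("wavenumber axis must be strictly increasing.")
  }
  if (any(!is.finite(intensity))) stop("intensities must all be finite.")
  structure(list(shift = shift, intensity = intensity, label = label,
                 concentration = concentration, seed = seed),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("Raman spectrum%s: %d points, %.0f-%.0f cm^-1\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              length(x$shift), min(x$shift), max(x$shift)))
  if (!is.null(x$concentration)) {
    cat(sprintf("  concentration: %g uM\n", x$concentration))
  }
  invisible(x)
}

#' @export
plot.raman_spectrum <- function(x, ...) {
  graphics::plot(x$shift, x$intensity, type = "l",
                 xlab = expression(paste("Raman shift (", cm^-1, ")")),
                 ylab = "intensity (counts)", ...)
}

# Whittaker smoother: minimise sum(w (y - z)^2) + lambda sum((D2 z)^2).
# Second-difference penalty, so constants and straight lines are reproduced
# exactly.  Sparse banded solve via Matrix.
whittaker <- function(y, lambda, w = rep(1, length(y))) {
  n <- length(y)
  d2 <- Matrix::bandSparse(n - 2, n,
                           k = 0:2,
                           diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                            rep(1, n - 2)))
  wm <- Matrix::Diagonal(n, w)
  z <- Matrix::solve(wm + lambda * Matrix::crossprod(d2), w * y)
  as.numeric(z)
}

#' Estimate a smooth spectral baseline
#'
#' Penalised least-squares (Whittaker) smoother with iterative peak masking:
#' after an initial symmetric fit, points whose residual exceeds
#' `k_mask` robust standard deviations are down-weighted and the fit is
#' repeated.  The result runs through the centre of the noise in band-free
#' regions (so residuals there have near-zero median) while refusing to climb
#' into emission bands.  Constants and linear ramps are reproduced exactly.
#'
#' @param spec a [raman_spectrum()].
#' @param lambda smoothness penalty (default `1e8`; stiff enough that weak
#'   unmasked bands are not partially absorbed into the baseline, while
#'   constants and linear ramps are always reproduced exactly).
#' @param k_mask residual threshold, in robust standard deviations, above
#'   which points are treated as signal (default 2).
#' @param mask_weight weight given to masked points (default 0.01).
#' @param n_iter number of masking iterations (default 5).
#' @return numeric baseline, same length as the spectrum.
#' @export
estimate_baseline <- function(spec, lambda = 1e8, k_mask = 2,
                              mask_weight = 0.01, n_iter = 5) {
  stopifnot(inherits(spec, "raman_spectrum"))
  y <- spec$intensity
  if (length(y) < 10) stop("spectrum too short for baseline smoothing.")
  w <- rep(1, length(y))
  z <- whittaker(y, lambda, w)
  for (i in seq_len(n_iter)) {
    r <- y - z
    s <- stats::mad(r)
    if (s == 0) break  # noiseless smooth spectrum: baseline already exact
    w_new <- ifelse(r > k_mask * s, mask_weight, 1)
    if (all(w_new == w)) break
    w <- w_new
    z <- whittaker(y, lambda, w)
  }
  z
}

default_quiet_windows <- function() list(c(600, 650), c(1650, 1700))

#' Average baseline-noise amplitude
#'
#' The noise parameter of the S/N pipeline: the mean absolute
#' baseline-subtracted residual over band-free ("quiet") wavenumber windows.
#' For Gaussian noise of standard deviation `sigma` its expectation is
#' `sigma * sqrt(2/pi)`.
#'
#' @param spec a [raman_spectrum()].
#' @param baseline baseline from [estimate_baseline()].
#' @param quiet_windows list of `c(low, high)` cm^-1 windows assumed free of
#'   bands; defaults to 600-650 and 1650-1700 cm^-1.
#' @return noise amplitude in counts.
#' @export
noise_amplitude <- function(spec, baseline = estimate_baseline(spec),
                            quiet_windows = default_quiet_windows()) {
  stopifnot(inherits(spec, "raman_spectrum"))
  idx <- unlist(lapply(quiet_windows, function(wdw) {
    which(spec$shift >= wdw[1] & spec$shift <= wdw[2])
  }))
  if (length(idx) == 0) {
    stop("quiet windows contain no points of the wavenumber axis.")
  }
  mean(abs(spec$intensity[idx] - baseline[idx]))
}

#' Intensity of an analyte band
#'
#' The signal parameter of the S/N pipeline: the baseline-subtracted height
#' of the band near `center` (default 1589 cm^-1, the reporter band of
#' 4-mercaptophenylboronic acid).  Methods:
#' \describe{
#'   \item{`"height"`}{(default) baseline-subtracted intensity interpolated
#'     at the nominal band centre.  Unbiased in noise, which keeps the
#'     S/N-concentration relation linear down to the detection limit.}
#'   \item{`"max"`}{maximum baseline-subtracted intensity in the window
#'     `center +/- half_width`.  Simple, but carries a positive
#'     extreme-value bias of order the noise amplitude near the LOD.}
#'   \item{`"area"`}{trapezoidal integral of the baseline-subtracted signal
#'     over the window (counts * cm^-1).}
#' }
#'
#' @inheritParams noise_amplitude
#' @param center band centre in cm^-1.
#' @param half_width half-width of the search/integration window in cm^-1.
#' @param method `"height"`, `"max"` or `"area"`.
#' @return band intensity in counts (or counts * cm^-1 for `"area"`).
#' @export
band_intensity <- function(spec, baseline = estimate_baseline(spec),
                           center = 1589, half_width = 15,
                           method = c("height", "max", "area")) {
  stopifnot(inherits(spec, "raman_spectrum"))
  method <- match.arg(method)
  lo <- center - half_width; hi <- center + half_width
  if (lo < min(spec$shift) || hi > max(spec$shift)) {
    stop("band window [", lo, ", ", hi, "] lies outside the spectral axis.")
  }
  r <- spec$intensity - baseline
  idx <- which(spec$shift >= lo & spec$shift <= hi)
  switch(method,
         height = stats::approx(spec$shift, r, xout = center)$y,
         max = max(r[idx]),
         area = pracma::trapz(spec$shift[idx], r[idx]))
}

#' Bundle a dilution series
#'
#' @param concentrations analyte concentrations in uM (positive, distinct).
#' @param spectra list of [raman_spectrum()] objects, one per concentration.
#' @return object of class `dilution_series`.
#' @export
dilution_series <- function(concentrations, spectra) {
  stopifnot(length(concentrations) == length(spectra),
            all(concentrations > 0),
            !anyDuplicated(concentrations))
  stopifnot(all(vapply(spectra, inherits, logical(1), "raman_spectrum")))
  structure(list(concentrations = concentrations, spectra = spectra),
            class = "dilution_series")
}

#' Measure S/N for every spectrum of a dilution series
#'
#' The baseline noise of the instrument does not depend on the analyte
#' concentration, so by default the S/N denominator is the noise amplitude
#' pooled (averaged) over the whole series; this keeps the S/N scale common
#' to all points of the calibration line.  Set `pool_noise = FALSE` to
#' divide each signal by its own spectrum's noise estimate instead.
#'
#' @param series a [dilution_series()].
#' @param center,half_width,method passed to [band_intensity()].
#' @param quiet_windows passed to [noise_amplitude()].
#' @param pool_noise use the series-mean noise amplitude as the common S/N
#'   denominator (default `TRUE`).
#' @param ... passed to [estimate_baseline()].
#' @return data frame with `concentration`, `signal`, `noise` (per
#'   spectrum), `sn`.
#' @export
series_sn <- function(series, center = 1589, half_width = 15,
                      method = "height",
                      quiet_windows = default_quiet_windows(),
                      pool_noise = TRUE, ...) {
  stopifnot(inherits(series, "dilution_series"))
  rows <- lapply(seq_along(series$spectra), function(i) {
    sp <- series$spectra[[i]]
    bl <- estimate_baseline(sp, ...)
    sig <- band_intensity(sp, bl, center = center, half_width = half_width,
                          method = method)
    noi <- noise_amplitude(sp, bl, quiet_windows = quiet_windows)
    data.frame(concentration = series$concentrations[i],
               signal = sig, noise = noi)
  })
  tab <- do.call(rbind, rows)
  denom <- if (pool_noise) mean(tab$noise) else tab$noise
  tab$sn <- tab$signal / denom
  tab
}

#' Limit of detection from an S/N-concentration fit
#'
#' Ordinary least squares of measured S/N on concentration (with intercept by
#' default), solved for the concentration at which the fitted line reaches
#' the detection criterion (default S/N = 3).
#'
#' @param series a [dilution_series()], or a data frame with columns
#'   `concentration` and `sn` (as from [series_sn()]).
#' @param criterion S/N detection threshold (default 3).
#' @param intercept fit with intercept (`TRUE`, default) or through the
#'   origin.
#' @param ... passed to [series_sn()] when `series` is a `dilution_series`.
#' @return object of class `lod_result`: list with `lod` (uM), `slope`
#'   (per uM), `intercept`, `criterion`, `r_squared`, `residual_sd`,
#'   `extrapolated` (TRUE when the fitted intercept already exceeds the
#'   criterion), the fitted `model` and the S/N table.
#' @export
fit_lod <- function(series, criterion = 3, intercept = TRUE, ...) {
  tab <- if (inherits(series, "dilution_series")) {
    series_sn(series, ...)
  } else {
    stopifnot(is.data.frame(series),
              all(c("concentration", "sn") %in% names(series)))
    series
  }
  if (nrow(tab) < 3) stop("need at least 3 concentrations to fit an LOD.")
  fml <- if (intercept) sn ~ concentration else sn ~ concentration - 1
  fit <- stats::lm(fml, data = tab)
  slope <- stats::coef(fit)[["concentration"]]
  b0 <- if (intercept) stats::coef(fit)[["(Intercept)"]] else 0
  if (slope <= 0) {
    stop("no detection: fitted S/N does not increase with concentration.")
  }
  extrapolated <- FALSE
  if (b0 >= criterion) {
    warning("fitted intercept (", signif(b0, 3), ") already exceeds the ",
            "criterion; LOD lies below the measured range (extrapolated).")
    extrapolated <- TRUE
  }
  lod <- (criterion - b0) / slope
  out <- list(lod = lod, slope = slope, intercept = b0,
              criterion = criterion,
              # suppress the "essentially perfect fit" note on exact lines
              r_squared = suppressWarnings(summary(fit)$r.squared),
              residual_sd = stats::sigma(fit),
              extrapolated = extrapolated,
              model = fit, sn_table = tab)
  class(out) <- "lod_result"
  out
}

#' @export
print.lod_result <- function(x, ...) {
  cat("Limit-of-detection fit (S/N vs concentration)\n")
  cat(sprintf("  slope     : %.4g per uM\n", x$slope))
  cat(sprintf("  intercept : %.4g\n", x$intercept))
  cat(sprintf("  LOD (S/N = %g): %.4g uM%s\n", x$criterion, x$lod,
              if (x$extrapolated) "  [extrapolated below range]" else ""))
  cat(sprintf("  R^2 = %.4f, residual sd = %.3g\n",
              x$r_squared, x$residual_sd))
  invisible(x)
}

#' Detect peaks in a baseline-subtracted spectrum
#'
#' Local maxima of the baseline-subtracted signal whose height exceeds
#' `min_snr` times the noise amplitude.  Peak width is the full width at
#' half maximum obtained by linear interpolation on each flank.
#'
#' @inheritParams noise_amplitude
#' @param noise noise amplitude from [noise_amplitude()].
#' @param min_snr detection threshold in noise units (default 3).
#' @param min_distance minimum separation between reported peaks, cm^-1.
#' @return data frame with `center` (cm^-1), `height` (counts), `width`
#'   (FWHM, cm^-1) and `snr`; zero rows when nothing is detected.
#' @export
detect_peaks <- function(spec, baseline = estimate_baseline(spec),
                         noise = noise_amplitude(spec, baseline),
                         min_snr = 3, min_distance = 8) {
  stopifnot(inherits(spec, "raman_spectrum"))
  r <- spec$intensity - baseline
  step <- stats::median(diff(spec$shift))
  empty <- data.frame(center = numeric(0), height = numeric(0),
                      width = numeric(0), snr = numeric(0))
  thr <- min_snr * noise
  if (thr <= 0) thr <- .Machine$double.eps * max(1, max(abs(r)))
  pk <- pracma::findpeaks(r, minpeakheight = thr,
                          minpeakdistance = max(1L, round(min_distance / step)))
  if (is.null(pk)) return(empty)
  out <- lapply(seq_len(nrow(pk)), function(k) {
    i <- pk[k, 2]; hgt <- pk[k, 1]
    half <- hgt / 2
    # walk out to the half-height crossings
    il <- i; while (il > 1 && r[il] > half) il <- il - 1
    ir <- i; while (ir < length(r) && r[ir] > half) ir <- ir + 1
    xl <- if (r[il] <= half && il < i) {
      stats::approx(r[c(il, il + 1)], spec$shift[c(il, il + 1)], xout = half)$y
    } else spec$shift[il]
    xr <- if (r[ir] <= half && ir > i) {
      stats::approx(r[c(ir - 1, ir)], spec$shift[c(ir - 1, ir)], xout = half)$y
    } else spec$shift[ir]
    data.frame(center = spec$shift[i], height = hgt,
               width = xr - xl, snr = hgt / noise)
  })
  out <- do.call(rbind, out)
  out[order(out$center), , drop = FALSE]
}

#' Packaged exosome band-assignment table
#'
#' The nine wavenumber windows and assignments of the major bands observed in
#' exosome SERS spectra (proteins, lipids, nucleic acids, carotenoids),
#' shipped as a CSV in `inst/extdata`.
#'
#' @return data frame with columns `low`, `high` (cm^-1) and `assignment`.
#' @export
exosome_band_table <- function() {
  path <- system.file("extdata", "exosome_band_assignments.csv",
                      package = "metasers")
  read_assignment_table(path)
}

validate_assignment_table <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("low", "high", "assignment") %in% names(table)))
  if (any(table$low >= table$high)) {
    stop("assignment table: every window needs low < high.")
  }
  o <- order(table$low)
  table <- table[o, , drop = FALSE]
  if (nrow(table) > 1 && any(table$low[-1] < table$high[-nrow(table)])) {
    stop("assignment table: windows overlap.")
  }
  table
}

#' Assign detected peaks to vibrational bands
#'
#' Labels each peak with the assignment of the unique wavenumber window
#' containing its centre, or `"unassigned"` when no window contains it.
#' Assignment is total and deterministic.
#'
#' @param peaks data frame from [detect_peaks()] (needs a `center` column).
#' @param table assignment table with columns `low`, `high`, `assignment`;
#'   defaults to [exosome_band_table()].
#' @return `peaks` with an added character column `assignment`.
#' @export
assign_bands <- function(peaks, table = exosome_band_table()) {
  table <- validate_assignment_table(table)
  stopifnot(is.data.frame(peaks), "center" %in% names(peaks))
  lab <- vapply(peaks$center, function(x) {
    hit <- which(table$low <= x & x <= table$high)
    if (length(hit) == 1) table$assignment[hit] else "unassigned"
  }, character(1))
  peaks$assignment <- lab
  peaks
}
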