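# Seeded generators for every fixture the toolkit needs: dilution-series
# spectra with a 1589 cm^-1 reporter band, exosome-like multi-band spectra,
# and co-registered AFM height / SSRM current map pairs with ground truth.

#' Describe a synthetic spectrum
#'
#' @param bands data frame with columns `center` (cm^-1), `amplitude`
#'   (counts) and `width` (Gaussian standard deviation, cm^-1).
#' @param baseline_coef polynomial baseline coefficients (constant first),
#'   evaluated in `(shift - min(shift))`.
#' @param noise_sigma standard deviation of additive Gaussian noise (counts).
#' @param seed integer seed; the same seed reproduces the same spectrum.
#' @param shift wavenumber grid, default 600-1700 cm^-1 in 1 cm^-1 steps.
#' @return object of class `spectrum_model`.
#' @export
spectrum_model <- function(bands = data.frame(center = numeric(0),
                                              amplitude = numeric(0),
                                              width = numeric(0)),
                           baseline_coef = 0, noise_sigma = 0, seed = 1,
                           shift = seq(600, 1700, by = 1)) {
  stopifnot(is.data.frame(bands),
            all(c("center", "amplitude", "width") %in% names(bands)) ||
              nrow(bands) == 0,
            noise_sigma >= 0)
  if (nrow(bands) > 0 && (any(bands$amplitude <= 0) || any(bands$width <= 0))) {
    stop("band amplitudes and widths must be positive.")
  }
  structure(list(bands = bands, baseline_coef = baseline_coef,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 shift = shift),
            class = "spectrum_model")
}

#' Generate a synthetic Raman spectrum
#'
#' Sum of Gaussian bands plus a polynomial baseline plus seeded Gaussian
#' noise on the model's wavenumber grid.  Bands centred outside the axis are
#' clipped with a warning.
#'
#' @param model a [spectrum_model()].
#' @param label,concentration metadata stored on the spectrum.
#' @return a [raman_spectrum()].
#' @export
gen_spectrum <- function(model, label = NULL, concentration = NULL) {
  stopifnot(inherits(model, "spectrum_model"))
  x <- model$shift
  y <- rep(0, length(x))
  for (p in seq_along(model$baseline_coef)) {
    y <- y + model$baseline_coef[p] * (x - min(x))^(p - 1)
  }
  if (nrow(model$bands) > 0) {
    outside <- model$bands$center < min(x) | model$bands$center > max(x)
    if (any(outside)) {
      warning(sum(outside), " band(s) centred outside the axis are clipped.")
    }
    for (k in seq_len(nrow(model$bands))) {
      b <- model$bands[k, ]
      y <- y + b$amplitude * exp(-(x - b$center)^2 / (2 * b$width^2))
    }
  }
  if (model$noise_sigma > 0) {
    old <- globalenv()$.Random.seed
    set.seed(model$seed)
    y <- y + stats::rnorm(length(x), sd = model$noise_sigma)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  raman_spectrum(x, y, label = label, concentration = concentration,
                 seed = model$seed)
}

#' Default band set of an exosome-like spectrum
#'
#' One Gaussian band placed at the midpoint of each of the nine assignment
#' windows of [exosome_band_table()].
#'
#' @param amplitude common band amplitude (counts).
#' @param width Gaussian standard deviation (cm^-1).
#' @return data frame suitable for [spectrum_model()].
#' @export
exosome_bands <- function(amplitude = 100, width = 6) {
  tab <- exosome_band_table()
  data.frame(center = (tab$low + tab$high) / 2,
             amplitude = amplitude, width = width)
}

#' Generate a dilution series with a linear S/N-concentration law
#'
#' For each concentration `c` the 1589 cm^-1 reporter band is scaled so that
#' the expected measured signal-to-noise ratio equals `sn_slope * c`: the
#' band height is `sn_slope * c * noise_sigma * sqrt(2/pi)`, since the
#' pipeline's noise parameter (mean absolute baseline residual) has
#' expectation `noise_sigma * sqrt(2/pi)` for Gaussian noise.
#'
#' @param concentrations analyte concentrations in uM; the default is the
#'   four-step series 50, 5, 0.5 and 0.05 uM.
#' @param sn_slope expected S/N per uM (default 15, so S/N = 3 at 0.2 uM).
#' @param noise_sigma Gaussian noise standard deviation in counts; must be
#'   positive for a measurable series (a zero-noise series is a fit-only
#'   fixture and is flagged with a warning).
#' @param seed integer seed; per-spectrum seeds are derived from it.
#' @param band_center,band_width reporter band centre and Gaussian sd, cm^-1.
#' @param baseline_coef polynomial baseline, as in [spectrum_model()].
#' @param shift wavenumber grid; default 600-1700 cm^-1 in 0.5 cm^-1 steps
#'   (a typical CCD sampling of the Stokes range).
#' @return a [dilution_series()] whose spectra carry their concentration.
#' @export
gen_dilution_series <- function(concentrations = c(50, 5, 0.5, 0.05),
                                sn_slope = 15, noise_sigma = 5, seed = 1,
                                band_center = 1589, band_width = 5,
                                baseline_coef = c(100, 0.05),
                                shift = seq(600, 1700, by = 0.5)) {
  stopifnot(all(concentrations > 0), sn_slope > 0, noise_sigma >= 0)
  if (noise_sigma == 0) {
    warning("noise_sigma = 0: measured S/N is undefined (division by zero); ",
            "treat this series as a fit-only fixture.")
  }
  expected_noise <- noise_sigma * sqrt(2 / pi)
  spectra <- lapply(seq_along(concentrations), function(i) {
    cc <- concentrations[i]
    amp <- sn_slope * cc * max(expected_noise, .Machine$double.eps)
    mdl <- spectrum_model(
      bands = data.frame(center = band_center, amplitude = amp,
                         width = band_width),
      baseline_coef = baseline_coef, noise_sigma = noise_sigma,
      seed = seed * 1000L + i, shift = shift)
    gen_spectrum(mdl, label = sprintf("4-mPBA %g uM", cc),
                 concentration = cc)
  })
  dilution_series(concentrations, spectra)
}

#' Describe a synthetic metasurface scan
#'
#' Geometry and object content of a co-registered AFM height / SSRM current
#' map pair.  The lattice is the sum of the closed-form film profile along
#' both axes (a separable stand-in for the doubly modulated surface),
#' normalised so its peak-to-valley equals `h`.  Objects are placed by
#' centre coordinates in nm from the map origin (top-left, x = column,
#' y = row).
#'
#' @param L,h lattice period and modulation in nm (defaults 400 and 80).
#' @param npix map size in pixels (square, default 1024).
#' @param pixel_size pixel size in nm (default 10, i.e. a 10x10 um field).
#' @param exosomes data frame with `x`, `y`, `diameter` (nm) and optionally
#'   `height` (defaults to `cap_ratio * diameter`).
#' @param silver_defects data frame with `x`, `y`, `radius` (nm): patches of
#'   missing metal -- conductivity drops with no topographic feature.
#' @param imperfections data frame like `exosomes`: polymer bumps formed
#'   before metal deposition -- topography without a conductivity drop.
#' @param cap_ratio bump height / diameter for objects without explicit
#'   heights (default 0.45; exosome caps flatten to roughly a third to a
#'   half of their diameter on drying).
#' @param roughness_rms rms of the smoothed height noise in nm (default 4).
#' @param current_noise_sd sd of multiplicative current noise (default 0.05).
#' @param current_floor normalized current on non-conducting footprints.
#' @param size_gate expected exosome diameter range in nm, kept as ground
#'   truth metadata (default 30-150).
#' @param seed integer seed.
#' @return object of class `surface_model`.
#' @export
surface_model <- function(L = 400, h = 80, npix = 1024, pixel_size = 10,
                          exosomes = NULL, silver_defects = NULL,
                          imperfections = NULL, cap_ratio = 0.45,
                          roughness_rms = 4, current_noise_sd = 0.05,
                          current_floor = 0.02, size_gate = c(30, 150),
                          seed = 1) {
  stopifnot(L > 0, h >= 0, npix >= 8, pixel_size > 0, cap_ratio > 0,
            roughness_rms >= 0)
  empty_obj <- data.frame(x = numeric(0), y = numeric(0),
                          diameter = numeric(0))
  if (is.null(exosomes)) exosomes <- empty_obj
  if (is.null(silver_defects)) {
    silver_defects <- data.frame(x = numeric(0), y = numeric(0),
                                 radius = numeric(0))
  }
  if (is.null(imperfections)) imperfections <- empty_obj
  add_height <- function(d) {
    if (nrow(d) > 0 && is.null(d$height)) d$height <- cap_ratio * d$diameter
    d
  }
  structure(list(L = L, h = h, a = tanh(pi * h / L), npix = npix,
                 pixel_size = pixel_size,
                 exosomes = add_height(exosomes),
                 silver_defects = silver_defects,
                 imperfections = add_height(imperfections),
                 cap_ratio = cap_ratio, roughness_rms = roughness_rms,
                 current_noise_sd = current_noise_sd,
                 current_floor = current_floor, size_gate = size_gate,
                 seed = as.integer(seed)),
            class = "surface_model")
}

# spherical-cap profile: base radius R, cap height H, radial distance r (nm)
spherical_cap <- function(r, R, H) {
  Rs <- (R^2 + H^2) / (2 * H)
  z <- sqrt(pmax(Rs^2 - r^2, 0)) - (Rs - H)
  ifelse(r <= R, pmax(z, 0), 0)
}

# isotropic smoothing of a matrix by a small Gaussian kernel (FFT circular
# convolution; kernel sd in pixels)
smooth_matrix <- function(m, sd_px) {
  n <- nrow(m); k <- ncol(m)
  fx <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  fy <- c(0:(k %/% 2), -((k - k %/% 2 - 1):1)) / k
  gk <- exp(-2 * pi^2 * sd_px^2 * outer(fx^2, fy^2, `+`))
  Re(stats::fft(stats::fft(m) * gk, inverse = TRUE)) / (n * k)
}

#' Generate a co-registered AFM/SSRM map pair with ground truth
#'
#' Builds the height map (periodic lattice + spherical-cap bumps for
#' exosomes and imperfections + seeded smoothed roughness) and the current
#' map (unit baseline, dropped to `current_floor` on exosome and
#' silver-defect footprints, multiplicative noise), pixel-for-pixel
#' co-registered, plus a ground-truth site table.  Objects overlapping the
#' map edge are rejected with a warning.
#'
#' @param model a [surface_model()].
#' @return list with `height` (a [height_map()]), `current` (a
#'   [current_map()]) and `truth` (data frame: `id`, `class`, `x`, `y`,
#'   `diameter`, `height`, all positions in nm).
#' @export
gen_surface_pair <- function(model) {
  stopifnot(inherits(model, "surface_model"))
  n <- model$npix; px <- model$pixel_size
  coord <- (seq_len(n) - 0.5) * px   # pixel-centre coordinates in nm
  spec <- fms_geometry(model$L, model$h, d = 1)  # d irrelevant for yu
  prof <- fms_profiles(spec, coord)$yu
  hmat <- (outer(rep(1, n), prof) + outer(prof, rep(1, n))) / 2
  # rows = y, cols = x; separable sum normalised to peak-to-valley h
  cmat <- matrix(1, n, n)
  extent <- n * px

  keep <- function(d, r_col) {
    if (nrow(d) == 0) return(d)
    r <- if (r_col == "radius") d$radius else d$diameter / 2
    ok <- d$x - r >= 0 & d$x + r <= extent & d$y - r >= 0 & d$y + r <= extent
    if (any(!ok)) {
      warning(sum(!ok), " object(s) overlapping the map edge were rejected.")
    }
    d[ok, , drop = FALSE]
  }
  exo <- keep(model$exosomes, "diameter")
  def <- keep(model$silver_defects, "radius")
  imp <- keep(model$imperfections, "diameter")

  add_cap <- function(mat, obj) {
    for (k in seq_len(nrow(obj))) {
      R <- obj$diameter[k] / 2; H <- obj$height[k]
      ic <- which(abs(coord - obj$y[k]) <= R + px)
      jc <- which(abs(coord - obj$x[k]) <= R + px)
      if (length(ic) == 0 || length(jc) == 0) next
      r <- sqrt(outer((coord[ic] - obj$y[k])^2, (coord[jc] - obj$x[k])^2, `+`))
      mat[ic, jc] <- mat[ic, jc] + spherical_cap(r, R, H)
    }
    mat
  }
  zero_current <- function(mat, xs, ys, radii) {
    for (k in seq_along(xs)) {
      ic <- which(abs(coord - ys[k]) <= radii[k])
      jc <- which(abs(coord - xs[k]) <= radii[k])
      if (length(ic) == 0 || length(jc) == 0) next
      r <- sqrt(outer((coord[ic] - ys[k])^2, (coord[jc] - xs[k])^2, `+`))
      sub <- mat[ic, jc]
      sub[r <= radii[k]] <- model$current_floor
      mat[ic, jc] <- sub
    }
    mat
  }
  hmat <- add_cap(hmat, exo)
  hmat <- add_cap(hmat, imp)
  cmat <- zero_current(cmat, exo$x, exo$y, exo$diameter / 2)
  cmat <- zero_current(cmat, def$x, def$y, def$radius)

  set.seed(model$seed)
  if (model$roughness_rms > 0) {
    rough <- smooth_matrix(matrix(stats::rnorm(n * n), n, n), sd_px = 2)
    rough <- rough / stats::sd(rough) * model$roughness_rms
    hmat <- hmat + rough
  }
  if (model$current_noise_sd > 0) {
    cmat <- cmat * (1 + matrix(stats::rnorm(n * n, sd = model$current_noise_sd),
                               n, n))
  }

  truth <- rbind(
    if (nrow(exo) > 0) data.frame(class = "exosome", x = exo$x, y = exo$y,
                                  diameter = exo$diameter, height = exo$height),
    if (nrow(def) > 0) data.frame(class = "silver_defect", x = def$x,
                                  y = def$y, diameter = 2 * def$radius,
                                  height = 0),
    if (nrow(imp) > 0) data.frame(class = "imperfection", x = imp$x,
                                  y = imp$y, diameter = imp$diameter,
                                  height = imp$height))
  if (is.null(truth)) {
    truth <- data.frame(class = character(0), x = numeric(0), y = numeric(0),
                        diameter = numeric(0), height = numeric(0))
  }
  truth <- cbind(id = seq_len(nrow(truth)), truth)
  list(height = height_map(hmat, px),
       current = current_map(cmat, px),
       truth = truth)
}

#' Randomly populated surface model
#'
#' Places non-overlapping exosomes (at depression centres, where deposition
#' concentrates), silver-deposition defects and fabrication imperfections on
#' the default lattice, with seeded sizes and positions.
#'
#' @param seed integer seed.
#' @param n_exosomes,n_defects,n_imperfections object counts.
#' @param exo_diameter_range exosome diameter range in nm (default 80-120,
#'   the typical mid-range of the 30-150 nm vesicle population).
#' @param ... further arguments passed to [surface_model()].
#' @return a [surface_model()].
#' @export
random_surface_model <- function(seed = 1, n_exosomes = 5, n_defects = 3,
                                 n_imperfections = 3,
                                 exo_diameter_range = c(80, 120), ...) {
  args <- list(...)
  L <- if (is.null(args$L)) 400 else args$L
  npix <- if (is.null(args$npix)) 1024 else args$npix
  px <- if (is.null(args$pixel_size)) 10 else args$pixel_size
  extent <- npix * px
  set.seed(seed)
  n_total <- n_exosomes + n_defects + n_imperfections
  # depression centres lie at odd multiples of L/2 on both axes
  n_dep <- floor(extent / L) - 1
  stopifnot(n_dep^2 >= n_total)
  cells <- expand.grid(ix = seq_len(n_dep), iy = seq_len(n_dep))
  pick <- cells[sample.int(nrow(cells), n_total), ]
  cx <- pick$ix * L + L / 2
  cy <- pick$iy * L + L / 2
  i1 <- seq_len(n_exosomes)
  i2 <- n_exosomes + seq_len(n_defects)
  i3 <- n_exosomes + n_defects + seq_len(n_imperfections)
  exo <- data.frame(x = cx[i1], y = cy[i1],
                    diameter = stats::runif(n_exosomes,
                                            exo_diameter_range[1],
                                            exo_diameter_range[2]))
  def <- data.frame(x = cx[i2], y = cy[i2],
                    radius = stats::runif(n_defects, 40, 80))
  imp <- data.frame(x = cx[i3], y = cy[i3],
                    diameter = stats::runif(n_imperfections, 80, 130))
  surface_model(exosomes = exo, silver_defects = def, imperfections = imp,
                seed = seed, ...)
}
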