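# Quasistatic plasmonics of a hollow metal nanocylinder and of the modulated
# thin-film metasurface obtained from it by the conformal map
# z1 = -i*log(w - a).  Time convention e^{-i*omega*t}: passive media have
# Im(eps) >= 0.  All lengths are in nm; permittivities are dimensionless
# complex numbers.

#' Optical quality factor of a metal
#'
#' `Q = |Re(eps)| / Im(eps)` for a metal permittivity `eps`.  Large `Q`
#' (weak absorption relative to polarisability) is what makes strong plasmon
#' resonance, and hence large SERS gain, possible.
#'
#' @param eps complex relative permittivity of the metal (e.g.
#'   `-29.8 + 0.38i` for silver at 785 nm).
#' @return dimensionless quality factor.
#' @examples
#' optical_quality(-29.8 + 0.38i)  # ~78.4, i.e. ~80 to one significant figure
#' @export
optical_quality <- function(eps) {
  eps <- as.complex(eps)
  if (Im(eps) <= 0) {
    stop("Im(eps) must be > 0 for a passive metal under the e^{-i*omega*t} ",
         "convention; got Im(eps) = ", Im(eps),
         ". If your data use the opposite convention, conjugate it first.")
  }
  abs(Re(eps)) / Im(eps)
}

#' Resonance determinant of the hollow nanocylinder
#'
#' The denominator shared by all scattered-field coefficients of the
#' three-medium (core / metal shell / exterior) cylinder problem:
#' `Det = alpha^2 (eps_e + eps_m)(eps_i + eps_m) + (eps_m - eps_e)(eps_i - eps_m)`.
#' Plasmon resonance corresponds to `|Det|` minimal.
#'
#' @param alpha ratio of external to internal shell radius, `re/ri` (> 0).
#' @param eps_i,eps_m,eps_e permittivities of the interior dielectric, the
#'   metal shell and the exterior medium.
#' @return complex determinant value (vectorised over `alpha`).
#' @export
resonance_det <- function(alpha, eps_i, eps_m, eps_e) {
  eps_i <- as.complex(eps_i); eps_m <- as.complex(eps_m)
  eps_e <- as.complex(eps_e)
  alpha^2 * (eps_e + eps_m) * (eps_i + eps_m) +
    (eps_m - eps_e) * (eps_i - eps_m)
}

#' Resonant radius ratio of the nanocylinder
#'
#' Radius ratio `alpha = re/ri` at which the loss-free determinant vanishes:
#' `alpha_res = sqrt((eps_e - eps_m')(eps_i - eps_m') /
#'                   ((eps_e + eps_m')(eps_i + eps_m')))`,
#' using only the real part `eps_m'` of the metal permittivity.
#'
#' @param eps_m_re real part of the metal permittivity; must satisfy
#'   `eps_m_re < -max(eps_i, eps_e)` for a resonance to exist.
#' @param eps_i,eps_e real permittivities of interior and exterior media.
#' @return dimensionless ratio, always > 1 when defined.
#' @export
alpha_res <- function(eps_m_re, eps_i, eps_e) {
  stopifnot(is.numeric(eps_m_re), is.numeric(eps_i), is.numeric(eps_e))
  ratio <- ((eps_e - eps_m_re) * (eps_i - eps_m_re)) /
    ((eps_e + eps_m_re) * (eps_i + eps_m_re))
  if (!is.finite(ratio) || ratio <= 0) {
    stop("no plasmon resonance: (eps_e - eps_m')(eps_i - eps_m') / ",
         "((eps_e + eps_m')(eps_i + eps_m')) must be positive, which ",
         "requires eps_m' < -max(eps_i, eps_e).")
  }
  sqrt(ratio)
}

#' Closed-form estimate of the determinant at resonance
#'
#' Large-quality-factor estimate `Det_res ~ 2i (eps_e + eps_i) eps_m' / Qm`,
#' valid when `Qm >> 1` and `|eps_m'| >> 1` (red / near-infrared range for
#' silver or gold).  The exact value is `resonance_det(alpha_res(...), ...)`;
#' this estimate is typically good to a factor of order one.
#'
#' @inheritParams resonance_det
#' @return complex estimate of the determinant minimum.
#' @export
det_res_estimate <- function(eps_i, eps_m, eps_e) {
  qm <- optical_quality(eps_m)
  if (qm < 10) {
    warning("det_res_estimate assumes Qm >> 1; got Qm = ", signif(qm, 3))
  }
  2i * (Re(eps_e) + Re(eps_i)) * Re(eps_m) / qm
}

#' Uniform field inside the hollow of the nanocylinder
#'
#' For a hollow shell excited by a uniform external field `E0`, the interior
#' field is uniform with `Ei/E0 = 4 alpha^2 eps_e eps_m / Det`.  Near
#' resonance its magnitude approaches `2 eps_e Qm / (eps_e + eps_i) ~ Qm`.
#'
#' @inheritParams resonance_det
#' @return complex field ratio `Ei/E0`.
#' @export
uniform_internal_field <- function(alpha, eps_i, eps_m, eps_e) {
  det <- resonance_det(alpha, eps_i, eps_m, eps_e)
  if (any(abs(det) == 0)) {
    stop("singular resonance: |Det| = 0, interior field diverges.")
  }
  4 * alpha^2 * as.complex(eps_e) * as.complex(eps_m) / det
}

#' Dipole amplitude of the internally driven nanocylinder
#'
#' Amplitude `A` of the uniform ("dipole") field excited inside the hollow by
#' an internal source of strength `a` (per unit source amplitude `U0`):
#' `A = a [alpha^2 (eps_e + eps_m)(eps_i - eps_m) -
#'         (eps_e - eps_m)(eps_i + eps_m)] / Det`.
#'
#' @param a dimensionless source offset, `0 <= a < 1`.
#' @inheritParams resonance_det
#' @return complex amplitude `A`.
#' @seealso [solve_matching_system()] for the full coefficient set obtained
#'   by boundary matching; its `A` reproduces this closed form.
#' @export
dipole_amplitude <- function(a, alpha, eps_i, eps_m, eps_e) {
  stopifnot(a >= 0, a < 1)
  eps_i <- as.complex(eps_i); eps_m <- as.complex(eps_m)
  eps_e <- as.complex(eps_e)
  det <- resonance_det(alpha, eps_i, eps_m, eps_e)
  if (any(abs(det) == 0)) stop("singular resonance: |Det| = 0.")
  a * (alpha^2 * (eps_e + eps_m) * (eps_i - eps_m) -
         (eps_e - eps_m) * (eps_i + eps_m)) / det
}

#' Solve the boundary-matching system of the driven nanocylinder
#'
#' The dipole harmonic of an internal source at offset `a` drives potentials
#' `U_i = A w + source`, `U_m = B w + C / w`, `U_e = D / w` in the hollow,
#' the metal shell and the exterior.  The four coefficients follow from
#' continuity of the potential and of the normal displacement at the two
#' interfaces `r = 1` and `r = alpha`.  This solver builds and solves that
#' 4x4 complex linear system; its `A` must agree with [dipole_amplitude()]
#' (independent closed form) to machine precision.
#'
#' @param a source offset in the cylinder frame, `0 <= a < 1`.
#' @param alpha radius ratio `re/ri` (> 1).
#' @inheritParams resonance_det
#' @param U0 source amplitude (default 1; coefficients scale linearly).
#' @return object of class `potential_solution`: list with complex `A`, `B`,
#'   `C`, `D`, the inputs, and `residual(n)` returning the maximum matching
#'   residual over `n` sampled polar angles.
#' @export
solve_matching_system <- function(a, alpha, eps_i, eps_m, eps_e, U0 = 1) {
  stopifnot(a >= 0, a < 1, alpha > 1)
  eps_i <- as.complex(eps_i); eps_m <- as.complex(eps_m)
  eps_e <- as.complex(eps_e)
  s <- a * U0  # dipole-harmonic source strength
  # unknowns x = (A, B, C, D); radial part of the dipole harmonic is r (for
  # w-terms) and 1/r (for 1/w-terms and the source)
  m <- matrix(c(
    1 + 0i, -1 + 0i,          -1 + 0i,            0 + 0i,   # potential, r = 1
    eps_i,  -eps_m,            eps_m,             0 + 0i,   # displacement, r = 1
    0 + 0i,  alpha,            1 / alpha,        -1 / alpha, # potential, r = alpha
    0 + 0i,  eps_m,           -eps_m / alpha^2,   eps_e / alpha^2 # displacement
  ), nrow = 4, byrow = TRUE)
  rhs <- c(-s, eps_i * s, 0 + 0i, 0 + 0i)
  x <- tryCatch(solve(m, rhs),
                error = function(e) stop("resonance singularity: matching ",
                                         "system is singular (",
                                         conditionMessage(e), ")"))
  sol <- list(A = x[1], B = x[2], C = x[3], D = x[4],
              a = a, alpha = alpha, U0 = U0,
              eps_i = eps_i, eps_m = eps_m, eps_e = eps_e)
  sol$residual <- function(n_angles = 64) {
    th <- seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]
    f <- cos(th)  # either circular harmonic gives the same residual scale
    with(sol, {
      r1 <- max(abs(((s + A) - (B + C)) * f))               # potential, r = 1
      r2 <- max(abs((eps_i * (A - s) - eps_m * (B - C)) * f))
      r3 <- max(abs(((B * alpha + C / alpha) - D / alpha) * f))
      r4 <- max(abs((eps_m * (B - C / alpha^2) + eps_e * D / alpha^2) * f))
      max(r1, r2, r3, r4)
    })
  }
  class(sol) <- "potential_solution"
  sol
}

#' @export
print.potential_solution <- function(x, ...) {
  cat("Potential solution (dipole harmonic, hollow nanocylinder)\n")
  cat(sprintf("  a = %.4f, alpha = %.4f, U0 = %g\n", x$a, x$alpha, x$U0))
  for (k in c("A", "B", "C", "D")) {
    v <- x[[k]]
    cat(sprintf("  %s = %.6g %+.6gi  (|%s| = %.6g)\n",
                k, Re(v), Im(v), k, abs(v)))
  }
  cat(sprintf("  max matching residual (64 angles): %.3g\n", x$residual(64)))
  invisible(x)
}

#' Metasurface geometry from film parameters
#'
#' Converts the physical film parameters -- period `L`, modulation `h` and
#' crest metal thickness `d` (all nm) -- into the cylinder-frame parameters
#' of the conformal map: source offset `a = tanh(pi h / L)` and radius ratio
#' `alpha = a + (1 - a) exp(2 pi d / L)`.
#'
#' @param L modulation period in nm (> 0).
#' @param h peak-to-valley modulation of the film in nm (>= 0; `h = 0` is the
#'   flat-film limit).
#' @param d metal thickness at the crest in nm (>= 0).
#' @return object of class `fms_spec`: list with `L`, `h`, `d`, `a`, `alpha`.
#' @examples
#' fms_geometry(400, 80, 15)  # a = 0.5569, alpha = 1.1177
#' @export
fms_geometry <- function(L, h, d) {
  stopifnot(L > 0, h >= 0, d >= 0)
  a <- tanh(pi * h / L)
  alpha <- a + (1 - a) * exp(2 * pi * d / L)
  structure(list(L = L, h = h, d = d, a = a, alpha = alpha),
            class = "fms_spec")
}

#' Film parameters from cylinder-frame parameters
#'
#' Inverse of [fms_geometry()]: `h = (L/pi) atanh(a)` and
#' `d = (L / 2 pi) log((alpha - a) / (1 - a))`.
#'
#' @param L period in nm.
#' @param a source offset, `0 <= a < 1`.
#' @param alpha radius ratio; must exceed `a`.
#' @return object of class `fms_spec`.
#' @export
fms_from_cylinder <- function(L, a, alpha) {
  stopifnot(L > 0, a >= 0, a < 1)
  if (alpha <= a) stop("alpha must exceed a.")
  h <- (L / pi) * atanh(a)
  d <- (L / (2 * pi)) * log((alpha - a) / (1 - a))
  fms_geometry(L, h, d)
}

#' @export
print.fms_spec <- function(x, ...) {
  cat("Flexible-metasurface geometry\n")
  cat(sprintf("  period L      : %.4g nm\n", x$L))
  cat(sprintf("  modulation h  : %.4g nm\n", x$h))
  cat(sprintf("  thickness d   : %.4g nm (at crest)\n", x$d))
  cat(sprintf("  a = tanh(pi h / L)            : %.6f\n", x$a))
  cat(sprintf("  alpha = a + (1-a) e^(2 pi d/L): %.6f\n", x$alpha))
  invisible(x)
}

#' Upper and lower film profiles of the metasurface
#'
#' Closed-form surfaces of the modulated film in nm, obtained as the images
#' of the two cylinder interfaces under the conformal map:
#' `yu(x) = -(L / 2 pi) log(sqrt(1 - a^2 sin^2 x1) - a cos x1)` (metal/front
#' interface) and
#' `yb(x) = -(L / 2 pi) log(sqrt(alpha^2 - a^2 sin^2 x1) - a cos x1)`
#' (metal/substrate interface), with `x1 = 2 pi x / L` taken on the principal
#' branch and tiled periodically.  Crests sit at `x = n L`, depressions at
#' `x = n L + L/2`; `yu(0) - yu(L/2) = h` and `yu(0) - yb(0) = d`.
#'
#' @param spec an `fms_spec` from [fms_geometry()].
#' @param x positions along the surface in nm (any real values).
#' @return list with numeric vectors `yu` and `yb` (nm).
#' @export
fms_profiles <- function(spec, x) {
  stopifnot(inherits(spec, "fms_spec"))
  x1 <- 2 * pi * x / spec$L
  a <- spec$a; alpha <- spec$alpha
  yu <- -(spec$L / (2 * pi)) * log(sqrt(1 - a^2 * sin(x1)^2) - a * cos(x1))
  yb <- -(spec$L / (2 * pi)) *
    log(sqrt(alpha^2 - a^2 * sin(x1)^2) - a * cos(x1))
  list(yu = yu, yb = yb)
}

#' Local intensity enhancement above the metasurface
#'
#' Dipole-term closed form for the intensity enhancement in front of the
#' film: `|E/E0|^2 = |A|^2 exp(-4 pi y / L)`, where `A` is the cylinder-frame
#' dipole amplitude and `y` the height above the map origin (nm).  The factor
#' `exp(-4 pi y / L)` is `|dw/dz1|^2` of the conformal map, so the intensity
#' grows toward the depressions (`y` most negative) and decays away from the
#' surface.  Points below the film surface `yu(x)` are masked (`NA`).
#'
#' @inheritParams fms_profiles
#' @param A complex dipole amplitude, e.g. from [dipole_amplitude()].
#' @param x,y coordinates in nm (recycled to a common length).
#' @return numeric vector of `|E/E0|^2`, `NA` below the surface.
#' @export
field_intensity <- function(spec, A, x, y) {
  stopifnot(inherits(spec, "fms_spec"))
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  yu <- fms_profiles(spec, x)$yu
  out <- Mod(A)^2 * exp(-4 * pi * y / spec$L)
  out[y < yu] <- NA_real_
  out
}

#' Grid map of field enhancement and SERS factor
#'
#' Evaluates [field_intensity()] on a rectangular grid over one or more
#' periods and returns a long-format data frame with the local SERS factor
#' `G = (|E/E0|^2)^2` and a mask for points above the film.
#'
#' @inheritParams field_intensity
#' @param nx,ny grid resolution.
#' @param x_range,y_range ranges in nm; defaults cover one period laterally
#'   and from the deepest depression to one half-period above the crest.
#' @return data frame with columns `x`, `y`, `above`, `intensity`, `G`.
#' @export
field_map <- function(spec, A, nx = 101, ny = 101,
                      x_range = c(-spec$L / 2, 3 * spec$L / 2),
                      y_range = NULL) {
  stopifnot(inherits(spec, "fms_spec"))
  if (is.null(y_range)) {
    p0 <- fms_profiles(spec, c(0, spec$L / 2))
    y_range <- c(p0$yu[2], p0$yu[1] + spec$L / 2)
  }
  g <- expand.grid(x = seq(x_range[1], x_range[2], length.out = nx),
                   y = seq(y_range[1], y_range[2], length.out = ny))
  yu <- fms_profiles(spec, g$x)$yu
  g$above <- g$y >= yu
  g$intensity <- Mod(A)^2 * exp(-4 * pi * g$y / spec$L)
  g$intensity[!g$above] <- NA_real_
  g$G <- g$intensity^2
  g
}

#' SERS enhancement factor from local intensity
#'
#' The Raman gain scales as the fourth power of the local field, i.e. the
#' square of the intensity enhancement: `G = (|E/E0|^2)^2`.
#'
#' @param intensity non-negative intensity enhancement `|E/E0|^2`.
#' @return `G`, same shape as `intensity`.
#' @export
sers_factor <- function(intensity) {
  if (any(intensity < 0, na.rm = TRUE)) stop("intensity must be >= 0.")
  intensity^2
}

#' Surface-averaged SERS factor at resonance
#'
#' At plasmon resonance the local field scales with the metal quality factor,
#' so the surface-averaged Raman gain is estimated as `G ~ Qm^4`
#' (about 1e7 for silver at 785 nm).
#'
#' @param Qm metal optical quality factor, see [optical_quality()].
#' @return `Qm^4`.
#' @export
sers_average <- function(Qm) {
  stopifnot(Qm > 0)
  Qm^4
}

#' Peak field at the depression bottom
#'
#' Closed-form estimate of the field amplitude at (or at height `dy` above)
#' the bottom of a film depression:
#' `Emax/E0 = 2 eps_i Qm a / ((a + 1)(eps_e + eps_i)) * exp(-2 pi dy / L)`,
#' with `a = tanh(pi h / L)`.
#'
#' @param L,h period and modulation in nm.
#' @param dy distance above the depression bottom in nm (>= 0).
#' @param eps_i permittivity of the front medium (1 for air, ~1.77 for water).
#' @param eps_e permittivity of the substrate (~2.5 for polycarbonate).
#' @param Qm metal quality factor.
#' @return field amplitude ratio `Emax/E0` (dimensionless).
#' @export
emax_estimate <- function(L, h, dy = 0, eps_i = 1, eps_e = 2.5, Qm) {
  stopifnot(L > 0, h >= 0, all(dy >= 0), Qm > 0)
  a <- tanh(pi * h / L)
  2 * eps_i * Qm * a / ((a + 1) * (eps_e + eps_i)) * exp(-2 * pi * dy / L)
}

#' Optimal metal thickness of the metasurface
#'
#' Crest thickness maximising the resonant response,
#' `d_max = (L / 2 pi) (eps_e + eps_i) / ((1 - a) |eps_m'|)`, and the
#' corresponding thickness at the depression bottom,
#' `d_bottom = exp(-2 pi h / L) d_max`.  Valid in the `|eps_m'| >> 1` regime.
#'
#' @inheritParams emax_estimate
#' @param eps_m_re real part of the metal permittivity (negative).
#' @return list with `d_max` and `d_bottom` in nm.
#' @export
optimal_thickness <- function(L, h, eps_i = 1, eps_e = 2.5, eps_m_re) {
  stopifnot(L > 0, h >= 0)
  if (abs(eps_m_re) < 5) {
    warning("optimal_thickness assumes |eps_m'| >> 1; got |eps_m'| = ",
            abs(eps_m_re))
  }
  a <- tanh(pi * h / L)
  d_max <- (L / (2 * pi)) * (eps_e + eps_i) / ((1 - a) * abs(eps_m_re))
  list(d_max = d_max, d_bottom = exp(-2 * pi * h / L) * d_max)
}

#' Scan metal thickness for plasmon resonance
#'
#' Maps each candidate crest thickness `d` to the radius ratio `alpha` via
#' [fms_geometry()], evaluates `|Det|`, and locates the thickness minimising
#' it by a dense grid followed by golden-section refinement (relative
#' tolerance 1e-9, ties toward smaller `d`).  The analytic resonance ratio
#' from [alpha_res()] is reported alongside for comparison.
#'
#' @param L,h period and modulation in nm.
#' @param eps_m complex metal permittivity.
#' @param eps_i,eps_e front and substrate permittivities.
#' @param d_range increasing range of thicknesses to scan, nm.
#' @param n_grid dense-grid size.
#' @return object of class `resonance_result`: list with `d_opt`, `alpha_opt`,
#'   `det_min_numeric`, `alpha_res` (analytic), `det_at_res`, `relative_gap`
#'   (= `|alpha_res - alpha_opt| / alpha_res`), and the scan table.
#' @export
resonance_scan <- function(L, h, eps_m, eps_i = 1, eps_e = 2.5,
                           d_range = c(5, 40), n_grid = 400) {
  stopifnot(L > 0, h >= 0, length(d_range) >= 2, all(diff(d_range) > 0),
            all(d_range > 0))
  obj <- function(d) {
    abs(resonance_det(fms_geometry(L, h, d)$alpha, eps_i, eps_m, eps_e))
  }
  d_grid <- seq(min(d_range), max(d_range), length.out = n_grid)
  vals <- vapply(d_grid, obj, numeric(1))
  i <- which.min(vals)  # which.min takes the first (smallest d) on ties
  if (i == 1L || i == n_grid) {
    warning("|Det| minimum lies at the boundary of d_range; ",
            "widen the scan range.")
    d_opt <- d_grid[i]
  } else {
    d_opt <- stats::optimize(obj, lower = d_grid[i - 1], upper = d_grid[i + 1],
                             tol = 1e-9 * max(d_grid))$minimum
  }
  a_opt <- fms_geometry(L, h, d_opt)$alpha
  a_res <- alpha_res(Re(eps_m), eps_i, eps_e)
  out <- list(
    d_opt = d_opt, alpha_opt = a_opt,
    det_min_numeric = resonance_det(a_opt, eps_i, eps_m, eps_e),
    alpha_res = a_res,
    det_at_res = resonance_det(a_res, eps_i, eps_m, eps_e),
    relative_gap = abs(a_res - a_opt) / a_res,
    scan = data.frame(d = d_grid, abs_det = vals)
  )
  class(out) <- "resonance_result"
  out
}

#' @export
print.resonance_result <- function(x, ...) {
  cat("Plasmon resonance scan\n")
  cat(sprintf("  optimal thickness d_opt : %.4g nm (alpha = %.6f)\n",
              x$d_opt, x$alpha_opt))
  cat(sprintf("  |Det| at scan minimum   : %.6g\n", abs(x$det_min_numeric)))
  cat(sprintf("  analytic alpha_res      : %.6f (|Det| = %.6g)\n",
              x$alpha_res, abs(x$det_at_res)))
  cat(sprintf("  relative gap in alpha   : %.3g\n", x$relative_gap))
  invisible(x)
}

#' Complex potential of the internal source
#'
#' The driving potential `U_ext = i U0 log(w - a)` in the cylinder frame.
#' Its leading log term produces a circular field of amplitude `~ 1/r` that
#' is independent of the metal permittivity; only the dipole term of its
#' multipole expansion (handled by [dipole_amplitude()]) is resonantly
#' enhanced, so the log term is exposed here but excluded from enhancement
#' maps.
#'
#' @param w complex coordinates in the cylinder frame.
#' @param a source offset.
#' @param U0 source amplitude.
#' @return complex potential values.
#' @export
source_potential <- function(w, a, U0 = 1) {
  1i * U0 * log(w - a)
}

#' Quasistatic validity report
#'
#' The closed forms assume a structure small compared to the wavelength and a
#' film thinner than the metal skin depth.  This helper prints the relevant
#' ratios without enforcing them (the quasistatic model is evaluated
#' regardless): `L / lambda`, and `d` against a conventional collisionless
#' skin-depth estimate `delta = lambda / (2 pi sqrt(|eps_m'|))`.  Published
#' statements of the skin-depth condition for this geometry are ambiguous,
#' so it is reported as a caveat only, never as a hard check.
#'
#' @param L period (nm), `d` metal thickness (nm).
#' @param d metal thickness in nm.
#' @param wavelength free-space wavelength in nm.
#' @param eps_m complex metal permittivity at that wavelength.
#' @return invisibly, a list with `L_over_lambda`, `skin_depth_nm`,
#'   `d_over_skin_depth`.
#' @export
quasistatic_validity <- function(L, d, wavelength, eps_m) {
  stopifnot(L > 0, d >= 0, wavelength > 0)
  delta <- wavelength / (2 * pi * sqrt(abs(Re(eps_m))))
  out <- list(L_over_lambda = L / wavelength,
              skin_depth_nm = delta,
              d_over_skin_depth = d / delta)
  cat(sprintf("quasistatic validity: L/lambda = %.3f (model assumes << 1);\n",
              out$L_over_lambda))
  cat(sprintf("  skin-depth estimate %.1f nm, d/delta = %.2f ",
              delta, out$d_over_skin_depth))
  cat("(estimate only; the thin-film closed forms assume d below delta)\n")
  invisible(out)
}
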