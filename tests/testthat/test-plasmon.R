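# Closed-form quasistatic plasmonics: resonance, conformal geometry, fields.

test_that("optical quality follows |Re|/Im and rejects the wrong convention", {
  expect_equal(optical_quality(-1 + 1i), 1)
  expect_equal(optical_quality(-30 + 0.3i), 100)
  expect_equal(optical_quality(eps_silver), 29.8 / 0.38)
  expect_error(optical_quality(-30 - 0.3i), "convention")
  expect_error(optical_quality(-30 + 0i), "convention")
})

test_that("determinant reduces correctly in algebraic limits", {
  # all media equal, alpha = 2: second product vanishes, first is 16 eps^2
  expect_equal(resonance_det(2, 1, 1, 1), 16 + 0i)
  # alpha = 1: Det = 2 eps_m (eps_e + eps_i), checked against expansion on
  # random complex media
  set.seed(7)
  for (k in 1:10) {
    ei <- complex(real = runif(1, 1, 3), imaginary = runif(1, 0, 0.1))
    em <- complex(real = runif(1, -40, -5), imaginary = runif(1, 0.1, 1))
    ee <- complex(real = runif(1, 1, 3), imaginary = runif(1, 0, 0.1))
    expect_equal(resonance_det(1, ei, em, ee), 2 * em * (ee + ei),
                 tolerance = 1e-12)
  }
})

test_that("analytic resonance ratio matches a dense |Det| scan", {
  expect_equal(alpha_res(-3, 1, 1), 2)
  a_res <- alpha_res(-29.8, 1, 2.5)
  expect_equal(a_res, 1.1249, tolerance = 1e-4)
  # dense grid oracle over alpha in [1, 1.3]
  grid <- seq(1, 1.3, length.out = 20001)
  vals <- abs(resonance_det(grid, 1, eps_silver, 2.5))
  expect_lt(abs(grid[which.min(vals)] - a_res) / a_res, 0.01)
  # deep-metal limit -> 1
  expect_equal(alpha_res(-1e9, 1, 2.5), 1, tolerance = 1e-6)
  # metal between -eps_e and -eps_i: ratio negative, no resonance
  expect_error(alpha_res(-1.5, 1, 2.5), "no plasmon resonance")
})

test_that("determinant-at-resonance estimate scales as 1/Qm and stays within
          a factor two of the exact minimum", {
  expect_equal(det_res_estimate(1, -30 + 0.3i, 1), -1.2i, tolerance = 1e-12)
  est <- abs(det_res_estimate(1, eps_silver, 2.5))
  exact <- abs(resonance_det(alpha_res(-29.8, 1, 2.5), 1, eps_silver, 2.5))
  expect_lt(max(est / exact, exact / est), 2)
  # 1/Qm scaling
  e1 <- abs(det_res_estimate(1, -30 + 0.3i, 2.5))
  e2 <- abs(det_res_estimate(1, -30 + 0.03i, 2.5))
  expect_equal(e1 / e2, 10, tolerance = 1e-10)
  expect_warning(det_res_estimate(1, -2 + 1i, 1), "Qm")
})

test_that("uniform internal field: homogeneous limit, resonance boost", {
  expect_equal(uniform_internal_field(1.7, 2, 2, 2), 1 + 0i)
  a_res <- alpha_res(-29.8, 1, 2.5)
  at_res <- abs(uniform_internal_field(a_res, 1, eps_silver, 2.5))
  qm <- optical_quality(eps_silver)
  # resonance estimate 2 eps_e Qm / (eps_e + eps_i), good to ~15%
  expect_equal(at_res, 2 * 2.5 * qm / 3.5, tolerance = 0.15)
  expect_gt(at_res, abs(uniform_internal_field(3, 1, eps_silver, 2.5)))
})

test_that("closed-form dipole amplitude equals the matching-system solution", {
  # trivial zeros
  expect_equal(dipole_amplitude(0.5, 1.5, 2, 2, 2), 0 + 0i)
  expect_equal(dipole_amplitude(0, 1.5, 1, eps_silver, 2.5), 0 + 0i)
  # oracle equivalence sweep over a 10 x 10 (a, alpha) grid
  for (a in seq(0.05, 0.95, length.out = 10)) {
    for (alpha in seq(1.02, 2, length.out = 10)) {
      A5 <- dipole_amplitude(a, alpha, 1, eps_silver, 2.5)
      sol <- solve_matching_system(a, alpha, 1, eps_silver, 2.5)
      expect_lt(abs(sol$A - A5) / abs(A5), 1e-8)
    }
  }
})

test_that("matching solver satisfies both boundary conditions", {
  sol <- solve_matching_system(0.5569, 1.1178, 1, eps_silver, 2.5)
  expect_lt(sol$residual(64), 1e-10 * abs(sol$U0))
  # homogeneous media: no induced uniform field; the outer coefficients
  # just continue the bare source term a/w across both interfaces
  hom <- solve_matching_system(0.4, 1.5, 2, 2, 2)
  expect_equal(abs(hom$A), 0, tolerance = 1e-14)
  expect_equal(abs(hom$B), 0, tolerance = 1e-14)
  expect_equal(hom$C, 0.4 + 0i, tolerance = 1e-12)
  expect_equal(hom$D, 0.4 + 0i, tolerance = 1e-12)
  expect_lt(hom$residual(64), 1e-12)
})

test_that("film geometry round-trips through the cylinder frame", {
  g <- fig1_spec()
  expect_equal(g$a, tanh(0.2 * pi), tolerance = 1e-12)
  expect_equal(g$a, 0.5569, tolerance = 1e-4)
  expect_equal(g$alpha, 1.1178, tolerance = 1e-4)
  # round trip (L, h, d) -> (a, alpha) -> (h, d) over a parameter grid
  for (L in c(200, 400, 800)) {
    for (h in c(10, 80, 150)) {
      for (d in c(5, 15, 40)) {
        g1 <- fms_geometry(L, h, d)
        g2 <- fms_from_cylinder(L, g1$a, g1$alpha)
        expect_equal(g2$h, h, tolerance = 1e-9)
        expect_equal(g2$d, d, tolerance = 1e-9)
      }
    }
  }
  # flat-film limit
  expect_equal(fms_geometry(400, 0, 15)$a, 0)
  expect_error(fms_geometry(-400, 80, 15))
})

test_that("film profiles reproduce modulation, thickness and flat limits", {
  g <- fig1_spec()
  p <- fms_profiles(g, c(0, 200))
  expect_equal(p$yu[1], -(400 / (2 * pi)) * log(1 - g$a), tolerance = 1e-12)
  expect_equal(p$yu[1], 51.82, tolerance = 1e-3)
  expect_equal(p$yu[2], -28.18, tolerance = 1e-3)
  expect_equal(p$yu[1] - p$yu[2], 80, tolerance = 1e-9)
  expect_equal(p$yu[1] - p$yb[1], 15, tolerance = 1e-9)
  expect_equal(p$yb[1], 36.81, tolerance = 1e-2)
  # profile extrema over a dense grid equal the closed-form values
  xx <- seq(-400, 800, by = 0.5)
  pp <- fms_profiles(g, xx)
  expect_equal(max(pp$yu) - min(pp$yu), g$h, tolerance = 1e-6)
  expect_true(all(pp$yu > pp$yb))
  # a = 0: flat parallel film
  g0 <- fms_geometry(400, 0, 15)
  p0 <- fms_profiles(g0, xx)
  expect_equal(max(abs(p0$yu)), 0, tolerance = 1e-12)
  expect_equal(unique(round(p0$yb, 9)),
               -(400 / (2 * pi)) * log(g0$alpha), tolerance = 1e-9)
})

test_that("field intensity follows the conformal-map factor exp(-4 pi y / L)", {
  g <- fig1_spec()
  A <- dipole_amplitude(g$a, g$alpha, 1, eps_silver, 2.5)
  # y = 0 gives |A|^2 (evaluated over a depression, where y = 0 is in air)
  expect_equal(field_intensity(g, A, x = 200, y = 0), abs(A)^2)
  # depression vs crest intensity ratio = exp(4 pi h / L) = 12.34
  p <- fms_profiles(g, c(0, 200))
  ratio <- field_intensity(g, A, 200, p$yu[2]) / field_intensity(g, A, 0, p$yu[1])
  expect_equal(ratio, exp(4 * pi * 80 / 400), tolerance = 1e-9)
  expect_equal(ratio, 12.34, tolerance = 1e-3)
  # masked below the surface
  expect_true(is.na(field_intensity(g, A, 200, -50)))
  # numerical |dw/dz1|^2 of w = a + exp(i z1) equals exp(-4 pi y / L)
  hstep <- 1e-6
  for (x1 in seq(-3, 3, length.out = 7)) {
    for (y1 in c(-0.4, 0, 0.7)) {
      z1 <- complex(real = x1, imaginary = y1)
      dw <- (exp(1i * (z1 + hstep)) - exp(1i * (z1 - hstep))) / (2 * hstep)
      y_nm <- y1 * 400 / (2 * pi)
      expect_equal(Mod(dw)^2, exp(-4 * pi * y_nm / 400), tolerance = 1e-6)
    }
  }
})

test_that("field map masks sub-surface points and peaks in depressions", {
  g <- fig1_spec()
  A <- dipole_amplitude(g$a, g$alpha, 1, eps_silver, 2.5)
  fm <- field_map(g, A, nx = 81, ny = 41)
  expect_true(all(fm$intensity[fm$above] > 0))
  expect_equal(fm$G, fm$intensity^2)
  expect_true(all(is.na(fm$intensity[!fm$above])))
  # along the surface, the maximum sits at the depression x = L/2 + nL
  xs <- seq(-200, 600, by = 1)
  surf <- fms_profiles(g, xs)$yu + 1e-9
  ii <- field_intensity(g, A, xs, surf)
  xmax <- xs[which.max(ii)]
  expect_true(min(abs(xmax - c(-200, 200, 600))) < 2)
  # strict growth toward smaller y (descending into a depression)
  ys <- seq(60, -20, by = -1)
  iy <- field_intensity(g, A, 200, ys)
  expect_true(all(diff(iy) > 0))
})

test_that("SERS factors square the intensity and rise with metal quality", {
  expect_equal(sers_factor(1), 1)
  expect_equal(sers_factor(12.34), 152.3, tolerance = 1e-3)
  expect_error(sers_factor(-1), ">= 0")
  qm <- optical_quality(eps_silver)
  expect_equal(sers_average(qm), qm^4)
  qq <- seq(10, 100, by = 10)
  expect_true(all(diff(sers_average(qq)) > 0))
})

test_that("peak-field estimate matches hand-evaluated values and limits", {
  qm <- optical_quality(eps_silver)
  e0 <- emax_estimate(400, 80, 0, 1, 2.5, qm)
  expect_equal(e0, 16.03, tolerance = 1e-3)
  expect_equal(emax_estimate(400, 80, 400 / (2 * pi), 1, 2.5, qm),
               e0 * exp(-1), tolerance = 1e-12)
  expect_equal(emax_estimate(400, 0, 0, 1, 2.5, qm), 0)
})

test_that("optimal thickness reproduces the design values", {
  ot <- optimal_thickness(400, 80, 1, 2.5, -29.8)
  expect_equal(ot$d_max, 16.87, tolerance = 1e-3)
  expect_equal(ot$d_bottom, exp(-0.4 * pi) * ot$d_max, tolerance = 1e-12)
  expect_equal(ot$d_bottom, 4.80, tolerance = 1e-2)
  # h -> 0: uniform film
  ot0 <- optimal_thickness(400, 0, 1, 2.5, -29.8)
  expect_equal(ot0$d_bottom, ot0$d_max)
  expect_warning(optimal_thickness(400, 80, 1, 2.5, -2), "eps_m")
})

test_that("thickness scan finds the resonance and flags boundary hits", {
  rs <- resonance_scan(400, 80, eps_silver, 1, 2.5, d_range = c(5, 40))
  # optimum alpha coincides with the analytic resonance ratio
  expect_lt(rs$relative_gap, 1e-3)
  # d whose alpha equals alpha_res: invert alpha = a + (1-a) exp(2 pi d / L)
  a <- tanh(0.2 * pi)
  d_star <- (400 / (2 * pi)) * log((rs$alpha_res - a) / (1 - a))
  expect_lt(abs(rs$d_opt - d_star), 0.01)
  expect_lt(abs(rs$d_opt - 15.9), 2)
  # scan minimum is a true interior minimum
  i <- which.min(rs$scan$abs_det)
  expect_gt(rs$scan$abs_det[i - 1], rs$scan$abs_det[i])
  expect_gt(rs$scan$abs_det[i + 1], rs$scan$abs_det[i])
  # lossless metal: |Det| minimum -> 0
  rs0 <- resonance_scan(400, 80, -29.8 + 1e-9i, 1, 2.5, d_range = c(5, 40))
  expect_lt(abs(rs0$det_min_numeric), 1e-4)
  expect_warning(resonance_scan(400, 80, eps_silver, 1, 2.5,
                                d_range = c(30, 40)),
                 "boundary")
})

test_that("validity report returns the stated ratios", {
  out <- quasistatic_validity(400, 15, 785, eps_silver)
  expect_equal(out$L_over_lambda, 400 / 785)
  expect_equal(out$skin_depth_nm, 785 / (2 * pi * sqrt(29.8)))
})
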