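# Correlative AFM/SSRM site identification.

test_that("lattice removal suppresses the periodic structure and keeps bumps", {
  p0 <- gen_surface_pair(surface_model(npix = 256, roughness_rms = 0,
                                       current_noise_sd = 0))
  r0 <- remove_lattice(p0$height, 400)
  input_rms <- stats::sd(as.numeric(unclass(p0$height)))
  expect_lt(stats::sd(as.numeric(r0)), 0.05 * input_rms)
  expect_lt(max(r0) - min(r0), 0.1 * 80)
  # flat map passes through unchanged (up to its mean)
  flat <- height_map(matrix(7, 64, 64), 10)
  expect_equal(max(abs(remove_lattice(flat, 400))), 0, tolerance = 1e-10)
  # a 100 nm exosome bump survives with >= 70% of its height
  pe <- gen_surface_pair(surface_model(
    npix = 256, exosomes = data.frame(x = 1000, y = 1000, diameter = 100),
    roughness_rms = 0, current_noise_sd = 0))
  re <- remove_lattice(pe$height, 400)
  expect_gt(max(re), 0.7 * 45)
  # unresolvable period
  expect_error(remove_lattice(flat, 15), "resolvable")
})

test_that("low-conductivity detection finds planted zero-current disks", {
  const <- current_map(matrix(1, 128, 128), 10)
  expect_equal(nrow(detect_low_conductivity(const)), 0)
  # five planted disks recovered at their centroids within one pixel
  centers <- cbind(x = c(200, 500, 800, 950, 300),
                   y = c(200, 350, 700, 150, 1000))
  mat <- matrix(1, 128, 128)
  cm <- current_map(mat, 10)
  md <- surface_model(npix = 128,
                      silver_defects = data.frame(x = centers[, "x"],
                                                  y = centers[, "y"],
                                                  radius = 40),
                      roughness_rms = 0, current_noise_sd = 0)
  pd <- gen_surface_pair(md)
  sites <- detect_low_conductivity(pd$current)
  expect_equal(nrow(sites), 5)
  ord <- order(sites$x)
  ord_t <- order(centers[, "x"])
  expect_true(all(abs(sites$x[ord] - centers[ord_t, "x"]) <= 10))
  expect_true(all(abs(sites$y[ord] - centers[ord_t, "y"]) <= 10))
  # site count is monotone in the threshold
  set.seed(2)
  noisy <- current_map(matrix(stats::runif(128 * 128, 0.02, 1), 128, 128), 10)
  n_strict <- nrow(detect_low_conductivity(noisy, drop_fraction = 0.9,
                                           min_area_px = 1))
  n_loose <- nrow(detect_low_conductivity(noisy, drop_fraction = 0.1,
                                          min_area_px = 1))
  expect_gte(n_loose, n_strict)
})

test_that("bump detection gates on height and lateral size", {
  flat <- height_map(matrix(0, 128, 128), 10)
  expect_equal(nrow(detect_bumps(flat)), 0)
  # a planted 100 nm exosome: one non-clustered site
  pe <- gen_surface_pair(surface_model(
    npix = 256, exosomes = data.frame(x = 1280, y = 1280, diameter = 100),
    roughness_rms = 0, current_noise_sd = 0))
  re <- remove_lattice(pe$height, 400)
  b <- detect_bumps(re)
  expect_equal(nrow(b), 1)
  expect_false(b$cluster)
  expect_lt(abs(b$x - 1280), 30)
  expect_true(b$fwhm >= 30 && b$fwhm <= 150)
  # a 300 nm mound is rejected by the size gate
  pm <- gen_surface_pair(surface_model(
    npix = 256, imperfections = data.frame(x = 1280, y = 1280,
                                           diameter = 300),
    roughness_rms = 0, current_noise_sd = 0))
  rm_ <- remove_lattice(pm$height, 400)
  expect_equal(nrow(detect_bumps(rm_)), 0)
  # two adjacent exosomes merge into one clustered blob
  pc <- gen_surface_pair(surface_model(
    npix = 256, exosomes = data.frame(x = c(1240, 1330), y = c(1280, 1280),
                                      diameter = 100),
    roughness_rms = 0, current_noise_sd = 0))
  rc <- remove_lattice(pc$height, 400)
  bc <- detect_bumps(rc, size_gate = c(30, 300))
  expect_true(any(bc$cluster))
})

test_that("decision table classifies the three site types", {
  ssrm <- data.frame(x = c(1000, 2000), y = c(1000, 2000),
                     radius = c(50, 50), area_px = c(70, 70))
  afm <- data.frame(x = c(1010, 3000), y = c(995, 3000),
                    height = c(45, 50), fwhm = c(90, 100),
                    cluster = c(FALSE, FALSE))
  sites <- classify_sites(ssrm, afm)
  expect_equal(sort(sites$class),
               c("exosome", "imperfection", "silver_defect"))
  exo <- sites[sites$class == "exosome", ]
  expect_true(exo$low_conductivity && exo$bump)
  sd_ <- sites[sites$class == "silver_defect", ]
  expect_true(sd_$low_conductivity && !sd_$bump)
  imp <- sites[sites$class == "imperfection", ]
  expect_true(!imp$low_conductivity && imp$bump)
})

test_that("classification is perfect on noise-free pairs and invariant to
          offset and scaling", {
  out <- run_classifier(small_surface_model(seed = 2))
  expect_true(all(out$score$precision == 1))
  expect_true(all(out$score$recall == 1))
  # global height offset and current scaling change nothing
  pair <- gen_surface_pair(small_surface_model(seed = 2))
  h2 <- height_map(unclass(pair$height) + 500, attr(pair$height, "pixel_size"))
  c2 <- current_map(unclass(pair$current) * 12, attr(pair$current, "pixel_size"))
  s1 <- classify_sites(detect_low_conductivity(pair$current),
                       detect_bumps(remove_lattice(pair$height, 400)))
  s2 <- classify_sites(detect_low_conductivity(c2),
                       detect_bumps(remove_lattice(h2, 400)))
  expect_equal(s1, s2)
})

test_that("classification stays >= 0.9 under default noise across seeds", {
  counts <- Reduce(`+`, lapply(1:6, function(s) {
    out <- run_classifier(small_surface_model(seed = s, roughness_rms = 4,
                                              current_noise_sd = 0.05))
    as.matrix(out$score[, c("n_truth", "n_called", "tp")])
  }))
  expect_true(all(counts[, "tp"] / counts[, "n_called"] >= 0.9))
  expect_true(all(counts[, "tp"] / counts[, "n_truth"] >= 0.9))
})

test_that("cross-sections measure the lattice modulation", {
  p0 <- gen_surface_pair(surface_model(npix = 256, roughness_rms = 0,
                                       current_noise_sd = 0))
  # diagonal through crests and depressions: swings equal h
  cs <- cross_section(p0$height, rbind(c(200, 200), c(2360, 2360)))
  expect_equal(cs$mean_modulation, 80, tolerance = 1 / 80)
  # flat map: no swings
  flat <- height_map(matrix(3, 64, 64), 10)
  csf <- cross_section(flat, rbind(c(50, 50), c(500, 500)))
  expect_equal(csf$mean_modulation, 0)
  expect_error(cross_section(flat, rbind(c(-10, 0), c(100, 100))), "outside")
  # with roughness the per-period swings spread around h
  pn <- gen_surface_pair(surface_model(npix = 256, roughness_rms = 8,
                                       current_noise_sd = 0, seed = 3))
  csn <- cross_section(pn$height, rbind(c(200, 200), c(2360, 2360)))
  expect_gt(csn$max_modulation, csn$min_modulation)
  expect_equal(csn$mean_modulation, 80, tolerance = 0.3)
})

test_that("period estimation fails cleanly on structureless maps", {
  set.seed(9)
  wn <- height_map(matrix(stats::rnorm(128 * 128), 128, 128), 10)
  expect_error(estimate_period(wn), "dominant")
})
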