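# Shared fixtures: silver at 785 nm on polycarbonate, and a reduced-size
# surface model for unit tests (256 px x 10 nm = 2.56 um, 6.4 lattice
# periods; acceptance tests use the full 1024 px default).

eps_silver <- -29.8 + 0.38i
eps_front <- 1
eps_substrate <- 2.5

fig1_spec <- function() fms_geometry(L = 400, h = 80, d = 15)

small_surface_model <- function(seed = 1, roughness_rms = 0,
                                current_noise_sd = 0, ...) {
  random_surface_model(seed = seed, n_exosomes = 2, n_defects = 1,
                       n_imperfections = 1, npix = 256, pixel_size = 10,
                       roughness_rms = roughness_rms,
                       current_noise_sd = current_noise_sd, ...)
}

run_classifier <- function(model, L = 400) {
  pair <- gen_surface_pair(model)
  res <- remove_lattice(pair$height, L)
  sites <- classify_sites(detect_low_conductivity(pair$current),
                          detect_bumps(res))
  list(sites = sites, truth = pair$truth,
       score = score_classification(sites, pair$truth))
}
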