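# Shared small fixtures, built in code.

# A tiny cube with distinct values per (pixel, band) for round-trip tests.
make_test_cube <- function(nr = 4, nc = 4, nb = 5, kind = "raw_counts") {
  vals <- array(seq_len(nr * nc * nb) %% 1009, dim = c(nr, nc, nb))
  wl <- seq(450, 650, length.out = nb)
  spectral_cube(vals, wl, kind = kind,
                meta = list(`integration time` = "40", `capture id` = "t"))
}

# A spatially uniform reflectance cube from one spectrum.
uniform_cube <- function(spectrum, wl, nr = 3, nc = 3) {
  a <- aperm(array(spectrum, dim = c(length(wl), nr, nc)), c(2, 3, 1))
  spectral_cube(a, wl, kind = "reflectance")
}

# Reduced synthetic scene used across tests (60 bands over 400-1000 nm).
reduced_scene_params <- function(n = 128, nb = 60, noise_sd = 20, seed = 7) {
  scene_params(n_rows = n, n_cols = n,
               wavelengths = seq(400, 1000, length.out = nb),
               noise_sd = noise_sd, seed = seed)
}

# Recover per-third profiles from a rendered scene through the full
# pipeline, using the truth third masks (ROI choice is not under test).
recover_profiles <- function(sc) {
  ff <- flat_field_correct(sc$raw, sc$dark, sc$gray,
                           tile = sc$truth$params$tile,
                           full_scale = sc$truth$params$full_scale)
  sat <- detect_saturation(sc$raw, sc$truth$params$full_scale)
  vis <- crop_spectral_range(ff$reflectance, 400, 780)
  tab <- cie_table(vis$wavelengths)
  lab <- cube_to_lab_image(vis, tab, combine_quality(ff$quality, sat))
  profiles <- lapply(names(sc$truth$masks), function(id)
    mean_lab_per_third(lab, sc$truth$thirds[[id]], id))
  names(profiles) <- names(sc$truth$masks)
  profiles
}

# Largest per-third Delta E*ab between recovered and truth profiles.
max_recovery_error <- function(profiles, truth_profiles) {
  max(vapply(names(profiles), function(id) {
    max(vapply(c("cervical", "middle", "incisal"), function(th)
      delta_e_ab(third_lab(profiles[[id]], th),
                 third_lab(truth_profiles[[id]], th))$value, numeric(1)))
  }, numeric(1)))
}
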