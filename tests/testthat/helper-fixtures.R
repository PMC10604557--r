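# Small fixtures shared across tests. Everything is generated in code.

# a clean profile with no background bands and no dispersion, for exactness
# tests
bare_profile <- function(name = "FM", centers = c(1565, 1588, 1639, 1670),
                         rel_area = c(0.361, 0.382, 0.047, 0.213), fwhm = 25,
                         area_scale = 12) {
  class_profile(
    name,
    tibble::tibble(center = centers, fwhm = fwhm, rel_area = rel_area),
    background_bands = tibble::tibble(center = numeric(), fwhm = numeric(),
                                      area = numeric()),
    area_scale = area_scale, amplitude_cv = 0, baseline_slope_sd = 0,
    noise_sd = 0, nuisance_sd = 0
  )
}

# tiny two-class spectra tibble, well separated, quick to fit
toy_cohort <- function(n_per_class = 4, noise_sd = 0, seed = 99) {
  profiles <- default_class_profiles(noise_sd = noise_sd)[c("FM", "LC")]
  simulate_cohort(profiles, sim_config(n_per_class = n_per_class, seed = seed))
}

# brute-force pairwise-concordance AUC (independent ROC oracle)
concordance_auc <- function(score, label, positive) {
  sp <- score[label == positive]
  sn <- score[label != positive]
  mean(outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b)))
}

# deterministic clean band sum (internal renderer)
render_clean_for_test <- function(profile, wavenumbers) {
  specfinger:::render_clean(profile, wavenumbers)
}

# run expr under a local seed without disturbing the session RNG
with_seed_test <- function(seed, expr) {
  specfinger:::with_seed(seed, expr)
}
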