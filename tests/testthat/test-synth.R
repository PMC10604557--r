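# Synthetic cohort generator: default profiles, rendering, determinism.

test_that("default class profiles carry the reported band structure", {
  profs <- default_class_profiles()
  expect_setequal(profs$FM$bands$center, c(1565, 1588, 1639, 1670))
  expect_setequal(profs$LC$bands$center, c(1581, 1635, 1670))
  expect_true(1545 %in% profs$HC$bands$center)
  for (p in profs) {
    expect_equal(sum(p$bands$rel_area), 1)
    expect_true(all(p$bands$fwhm > 0))
  }
  # HC 1545 share and the 70/10/20 remainder split
  hc <- profs$HC$bands
  expect_equal(hc$rel_area[hc$center == 1545], 0.041)
  expect_equal(hc$rel_area[hc$center == 1580] / hc$rel_area[hc$center == 1639],
               7, tolerance = 1e-12)
})

test_that("noise-free rendering is the deterministic band sum", {
  prof <- bare_profile()
  cfg <- sim_config()
  spec <- render_spectrum(prof, cfg)
  wn <- spectra_wavenumbers(spec)
  manual <- rowSums(vapply(seq_len(4), function(k) {
    gaussian_band(wn, gaussian_height(prof$bands$rel_area[k] * prof$area_scale,
                                      25),
                  prof$bands$center[k], 25)
  }, numeric(length(wn))))
  expect_equal(drop(spectra_matrix(spec)), manual, ignore_attr = TRUE)
})

test_that("rendered band area matches its spec by trapezoidal integration", {
  prof <- bare_profile(centers = 1600, rel_area = 1, fwhm = 30, area_scale = 10)
  spec <- render_spectrum(prof, sim_config(grid_min = 1400, grid_max = 1800,
                                           grid_step = 0.5))
  wn <- rev(spectra_wavenumbers(spec))
  y <- rev(drop(spectra_matrix(spec)))
  trap <- sum(diff(wn) * (head(y, -1) + tail(y, -1)) / 2)
  expect_equal(trap, 10, tolerance = 1e-3)
})

test_that("noise-free FM band positions are resolved at the profile centers", {
  # the 1565/1588 doublet overlaps in raw absorbance; the second-derivative
  # signal resolves all four centers, each within one grid step
  spec <- render_spectrum(bare_profile(), sim_config())
  sig <- prepare_signal(spec)
  imax <- which(diff(sign(diff(sig$signal))) == -2) + 1
  peaks <- sig$wavenumber[imax][order(sig$signal[imax], decreasing = TRUE)][1:4]
  # the weak 1639 band overlaps 1670, so its derivative maximum can shift by
  # a grid step or two; the multipeak fit recovers the true center
  for (cm in c(1565, 1588, 1639, 1670)) {
    expect_true(any(abs(peaks - cm) <= 4))
  }
})

test_that("region band fractions reproduce the profile rel_areas within 1%", {
  prof <- bare_profile()
  cfg <- sim_config()
  areas <- vapply(seq_len(nrow(prof$bands)), function(k) {
    spec <- render_spectrum(prof, cfg, bands = prof$bands[k, ])
    reg <- select_region(spec, 1500, 1700)
    wn <- rev(spectra_wavenumbers(reg))
    y <- rev(drop(spectra_matrix(reg)))
    sum(diff(wn) * (head(y, -1) + tail(y, -1)) / 2)
  }, numeric(1))
  expect_equal(areas / sum(areas), prof$bands$rel_area, tolerance = 0.01)
})

test_that("a band center outside the grid is rejected", {
  prof <- bare_profile(centers = c(1565, 2100), rel_area = c(0.5, 0.5))
  expect_error(render_spectrum(prof, sim_config()), "outside the simulation grid")
})

test_that("cohorts are bit-identical under a fixed seed and labelled correctly", {
  cfg <- sim_config(n_per_class = 5, seed = 7)
  a <- simulate_cohort(config = cfg)
  b <- simulate_cohort(config = cfg)
  expect_identical(a$spectra, b$spectra)
  expect_identical(a$truth, b$truth)
  expect_equal(unname(table(a$spectra$label)[c("FM", "LC")]), c(5L, 5L),
               ignore_attr = TRUE)
  d <- simulate_cohort(config = sim_config(n_per_class = 5, seed = 8))
  expect_false(identical(a$spectra, d$spectra))
})

test_that("simulated noise sd matches the profile within 10%", {
  prof <- default_class_profiles()$FM
  cfg <- sim_config(n_per_class = 50, seed = 3)
  co <- simulate_cohort(list(FM = prof), cfg)
  x <- spectra_matrix(co$spectra)
  wn <- spectra_wavenumbers(co$spectra)
  nuis <- nuisance_loading(prof, wn)
  clean <- render_clean_for_test(prof, wn)
  resid <- vapply(seq_len(nrow(x)), function(i) {
    tr <- co$truth[co$truth$sample_id == co$spectra$sample_id[i], ]
    model <- tr$scale[1] * clean + tr$slope[1] * (wn - mean(wn)) +
      tr$nuisance_score[1] * nuis
    stats::sd(x[i, ] - model)
  }, numeric(1))
  expect_equal(mean(resid), prof$noise_sd, tolerance = 0.1)
})

test_that("band jitter draws per-sample parameters around the profile", {
  prof <- default_class_profiles()$FM
  co <- simulate_cohort(list(FM = prof),
                        sim_config(n_per_class = 40, seed = 5),
                        jitter_bands = TRUE)
  b1565 <- co$truth[abs(co$truth$center - 1565) < 10, ]
  expect_gt(stats::sd(b1565$center), 1)     # dispersion present
  expect_equal(mean(b1565$center), 1565, tolerance = 2)
})
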