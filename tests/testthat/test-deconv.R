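# Band deconvolution: signal preparation, seeding, fitting, group summaries.

test_that("prepared signal of a single band peaks at the band center", {
  prof <- bare_profile(centers = 1600, rel_area = 1, fwhm = 25)
  sig <- prepare_signal(render_spectrum(prof, sim_config()))
  expect_lte(abs(sig$wavenumber[which.max(sig$signal)] - 1600), 2)
  expect_gte(min(sig$signal), 0)
})

test_that("a flat spectrum prepares to the zero signal", {
  wn <- seq(1800, 1400, by = -2)
  flat <- tibble::tibble(wavenumber = wn, absorbance = rep(0.3, length(wn)))
  sig <- prepare_signal(flat)
  expect_equal(sig$signal, rep(0, nrow(sig)), tolerance = 1e-12)
  expect_error(seed_peaks(sig), "no peaks")
})

test_that("a linear ramp does not change the prepared signal", {
  prof <- bare_profile()
  spec <- render_spectrum(prof, sim_config())
  wn <- spectra_wavenumbers(spec)
  ramped <- spec
  ramped[, -(1:2)] <- ramped[, -(1:2)] + as.list(0.001 * (wn - 1600) / 400)
  pp <- preprocess_config(norm = "none")   # ramp changes the norm, so skip it
  s1 <- prepare_signal(spec, pp = pp)
  s2 <- prepare_signal(ramped, pp = pp)
  expect_equal(s2$signal, s1$signal, tolerance = 1e-10)
})

test_that("seeding finds separated bands and the fit prunes pedestal humps", {
  prof <- bare_profile(centers = c(1565, 1639), rel_area = c(0.6, 0.4))
  sig <- prepare_signal(render_spectrum(prof, sim_config()))
  seeds <- seed_peaks(sig)
  # both true centers seeded within one grid step
  expect_true(any(abs(seeds$center - 1565) <= 2))
  expect_true(any(abs(seeds$center - 1639) <= 2))
  # the min-offset baseline can leave pedestal humps between distant bands;
  # the fit must discard them and return exactly the two real bands
  fit <- fit_bands(sig, seeds)
  expect_equal(nrow(fit$bands), 2L)
  expect_equal(fit$bands$center, c(1565, 1639), tolerance = 1e-3)
})

test_that("seeds closer than merge_distance collapse to their weighted mean", {
  x <- seq(1700, 1500, by = -1)
  s <- gaussian_band(x, 1, 1600, 3) + gaussian_band(x, 0.8, 1604, 3)
  sig <- tibble::tibble(wavenumber = x, signal = s)
  seeds <- seed_peaks(sig, fit_config(merge_distance = 8))
  expect_equal(nrow(seeds), 1L)
  expect_true(seeds$center > 1600 & seeds$center < 1604)  # weighted mean
  # without merging the two maxima stay distinct
  expect_equal(nrow(seed_peaks(sig, fit_config(merge_distance = 2))), 2L)
})

test_that("single-band recovery is essentially exact", {
  prof <- bare_profile(centers = 1600, rel_area = 1, fwhm = 30, area_scale = 10)
  spec <- render_spectrum(prof, sim_config())
  sig <- prepare_signal(spec)
  fit <- fit_bands(sig, seed_peaks(sig))
  expect_equal(nrow(fit$bands), 1L)
  expect_lte(abs(fit$bands$center - 1600), 0.5)
  # area on the absorbance scale, undoing the unit-norm factor
  area_abs <- fit$bands$area * attr(sig, "norm_factor")
  expect_equal(area_abs, 10, tolerance = 0.01)
  expect_true(fit$diagnostics$converged)
  expect_equal(fit$bands$pct_area, 100)
})

test_that("noise-free multi-band mixtures are recovered within tolerance", {
  cases <- list(
    list(centers = c(1565, 1588, 1639, 1670),
         rel = c(0.361, 0.382, 0.047, 0.213), fwhm = 25),
    list(centers = c(1540, 1585, 1630, 1675),
         rel = c(0.1, 0.4, 0.2, 0.3), fwhm = 20),
    list(centers = c(1550, 1600, 1655), rel = c(0.25, 0.5, 0.25), fwhm = 32),
    list(centers = c(1530, 1560, 1590, 1620, 1650),
         rel = c(0.3, 0.15, 0.25, 0.1, 0.2), fwhm = 16)
  )
  for (cs in cases) {
    prof <- bare_profile(centers = cs$centers, rel_area = cs$rel,
                         fwhm = cs$fwhm)
    sig <- prepare_signal(render_spectrum(prof, sim_config()))
    fit <- fit_bands(sig, seed_peaks(sig))
    expect_equal(nrow(fit$bands), length(cs$centers))
    expect_true(all(abs(fit$bands$center - cs$centers) <= 2))
    truth_pct <- 100 * cs$rel / sum(cs$rel)
    expect_true(all(abs(fit$bands$pct_area - truth_pct) <= 2))
  }
})

test_that("percentage areas always sum to 100 and survive amplitude doubling", {
  prof <- bare_profile()
  sig <- prepare_signal(render_spectrum(prof, sim_config()))
  fit <- fit_bands(sig, seed_peaks(sig))
  expect_equal(sum(fit$bands$pct_area), 100, tolerance = 1e-6)
  prof2 <- bare_profile(area_scale = 24)
  sig2 <- prepare_signal(render_spectrum(prof2, sim_config()))
  fit2 <- fit_bands(sig2, seed_peaks(sig2))
  expect_equal(fit2$bands$pct_area, fit$bands$pct_area, tolerance = 1e-4)
})

test_that("fit diagnostics are populated and descent is monotone", {
  prof <- bare_profile()
  sig <- prepare_signal(render_spectrum(prof, sim_config()))
  seeds <- seed_peaks(sig)
  fit <- fit_bands(sig, seeds)
  d <- fit$diagnostics
  expect_gte(d$chi_square, 0)
  expect_lte(d$iterations, 3 * 400 * (3 * nrow(seeds) + 4))  # optim eval cap
  expect_true(is.finite(d$f_statistic) || d$chi_square == 0)
  # final chi-square never exceeds the seed model's
  s2 <- sig$signal / max(sig$signal)
  seed_model <- rowSums(vapply(seq_len(nrow(seeds)), function(k) {
    specfinger:::neg_d2_band(sig$wavenumber, seeds$amplitude[k] / max(sig$signal),
                             seeds$center[k], seeds$fwhm[k])
  }, numeric(nrow(sig))))
  sse0 <- sum((s2 - specfinger:::endpoint_line_correct(sig$wavenumber,
                                                       seed_model))^2)
  expect_lte(d$chi_square / max(sig$signal)^2, sse0 + 1e-9)
})

test_that("degenerate fits raise explicit errors", {
  wn <- seq(1800, 1400, by = -2)
  flat <- tibble::tibble(wavenumber = wn, absorbance = rep(1, length(wn)))
  sig <- prepare_signal(flat)
  forced <- tibble::tibble(center = 1600, amplitude = 0, fwhm = 25)
  expect_error(fit_bands(sig, forced), "degenerate")
  expect_error(fit_bands(sig, forced[0, ]), "at least one seed")
  narrow <- tibble::tibble(wavenumber = seq(1700, 1500, -2),
                           absorbance = rnorm(101))
  expect_error(prepare_signal(narrow), "margin")
})

test_that("group deconvolution recovers the class band structure across noisy samples", {
  profiles <- default_class_profiles()[c("FM", "LC")]
  co <- simulate_cohort(profiles, sim_config(n_per_class = 12, seed = 21))
  bands <- deconvolve(co$spectra)
  smry <- summarize_bands(bands, min_frac = 0.5)
  fm <- smry[smry$label == "FM", ]
  lc <- smry[smry$label == "LC", ]
  # four FM bands near the profile centers, mean centers within +/- 3
  expect_equal(nrow(fm), 4L)
  expect_true(all(vapply(c(1565, 1588, 1639, 1670), function(cm) {
    any(abs(fm$center_mean - cm) <= 3)
  }, logical(1))))
  # three LC bands, none near the FM-unique 1565 marker
  expect_equal(nrow(lc), 3L)
  expect_false(any(abs(lc$center_mean - 1565) <= 5))
  # identical inputs give zero spread
  one <- bands[bands$sample_id == bands$sample_id[1], ]
  two <- dplyr::mutate(one, sample_id = "copy")
  smry2 <- summarize_bands(dplyr::bind_rows(one, two))
  expect_true(all(smry2$center_sd == 0))
  expect_true(all(smry2$pct_area_sd == 0))
  expect_error(deconvolve(co$spectra, classes = "HC"), "not present")
})

test_that("between-patient band jitter keeps the class contrast detectable", {
  # at the reported center dispersions the FM 1565/1588 doublet chains into
  # one cluster under single-linkage matching; the disease contrast (strong
  # low-1580s area in FM absent at 1565 in LC) must survive regardless
  profiles <- default_class_profiles()[c("FM", "LC")]
  co <- simulate_cohort(profiles, sim_config(n_per_class = 12, seed = 21),
                        jitter_bands = TRUE)
  bands <- deconvolve(co$spectra)
  smry <- summarize_bands(bands, min_frac = 0.5)
  lc <- smry[smry$label == "LC", ]
  expect_false(any(abs(lc$center_mean - 1565) <= 5))
  fm_low <- bands[bands$label == "FM" & bands$center < 1580, ]
  expect_gt(dplyr::n_distinct(fm_low$sample_id), 6)   # 1565 region occupied
  lc_low <- bands[bands$label == "LC" & bands$center < 1570, ]
  expect_lt(dplyr::n_distinct(lc_low$sample_id), 6)
})
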