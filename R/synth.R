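# Synthetic FT-MIR cohort generator.
#
# Each class is a Gaussian band mixture in the 1500-1700 cm-1 fingerprint
# region (centers and relative areas from the deconvolution band table of the
# source cohort) on top of broad background features, with per-sample
# multiplicative amplitude variation, linear baseline drift, a class-unrelated
# structured nuisance direction (for OSC to remove) and additive white noise:
#
#   A(x) = scale * [ sum_k g(x; c_k, w_k, a_k) + background(x) ]
#          + slope * (x - mean(x)) + score * nuisance(x) + eps(x)

#' Simulation configuration
#'
#' @param grid_min,grid_max Wavenumber bounds of the simulated grid (cm-1).
#'   The default 1400-1800 window covers the 1500-1700 fingerprint region plus
#'   filter margins; a full 4000-700 range is supported but not needed by any
#'   downstream stage.
#' @param grid_step Grid spacing (cm-1). The acquisition resolution of the
#'   source instrument (8 cm-1) constrains band shapes, not the digitized
#'   spacing; 2 cm-1 keeps the 5/7-point Savitzky-Golay windows local.
#' @param n_per_class Samples per class.
#' @param seed Master RNG seed; per-sample substreams are derived from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(grid_min = 1400, grid_max = 1800, grid_step = 2,
                       n_per_class = 50, seed = 1) {
  stopifnot(grid_min < grid_max, grid_step > 0, n_per_class >= 1)
  structure(list(grid_min = grid_min, grid_max = grid_max,
                 grid_step = grid_step, n_per_class = as.integer(n_per_class),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Wavenumber grid of a simulation configuration (descending)
#'
#' @param config A [sim_config()].
#' @return Numeric vector of wavenumbers, descending.
#' @export
sim_grid <- function(config) {
  seq(config$grid_max, config$grid_min, by = -config$grid_step)
}

#' Construct a class profile
#'
#' @param name Class label (`"FM"`, `"LC"` or `"HC"`).
#' @param bands Tibble of fingerprint bands with columns `center`, `fwhm`,
#'   `rel_area` (fraction of the class fingerprint area; renormalized to sum
#'   to 1) and optionally `center_sd`, `rel_area_sd` used when band jitter is
#'   requested.
#' @param background_bands Tibble with columns `center`, `fwhm`, `area`
#'   describing broad non-discriminating features (lipid ester, C-H bending,
#'   O-H/C-H stretch...). Bands outside the simulation grid are skipped.
#' @param area_scale Total integrated fingerprint band area per spectrum
#'   (absorbance x cm-1). The default 12 puts the strongest band near 0.17
#'   absorbance units, typical of a dried-film ATR measurement.
#' @param amplitude_cv Coefficient of variation of the per-sample global scale.
#' @param baseline_slope_sd Standard deviation of the per-sample linear
#'   baseline slope (absorbance per cm-1).
#' @param noise_sd Standard deviation of additive white noise (absorbance).
#' @param nuisance_center,nuisance_fwhm Center/FWHM of the broad Gaussian
#'   nuisance direction (class-unrelated structured variance); the loading is
#'   normalized to unit Euclidean norm on the grid.
#' @param nuisance_sd Standard deviation of the per-sample nuisance score.
#' @return A `class_profile` list.
#' @export
class_profile <- function(name, bands, background_bands = background_band_table(),
                          area_scale = 12, amplitude_cv = 0.05,
                          baseline_slope_sd = 2e-5, noise_sd = 0.002,
                          nuisance_center = 1740, nuisance_fwhm = 100,
                          nuisance_sd = 0.05) {
  bands <- tibble::as_tibble(bands)
  stopifnot(nrow(bands) >= 1, all(c("center", "fwhm", "rel_area") %in% names(bands)),
            all(bands$fwhm > 0), all(bands$rel_area >= 0),
            amplitude_cv >= 0, baseline_slope_sd >= 0, noise_sd >= 0,
            nuisance_sd >= 0)
  bands$rel_area <- bands$rel_area / sum(bands$rel_area)
  structure(list(name = name, bands = bands,
                 background_bands = tibble::as_tibble(background_bands),
                 area_scale = area_scale, amplitude_cv = amplitude_cv,
                 baseline_slope_sd = baseline_slope_sd, noise_sd = noise_sd,
                 nuisance_center = nuisance_center, nuisance_fwhm = nuisance_fwhm,
                 nuisance_sd = nuisance_sd),
            class = "class_profile")
}

#' Broad background band table shared by all classes
#'
#' Centers follow the assignments of the representative whole-range spectrum
#' (O-H/C-H stretch, lipid ester C=O at 1740, methyl bending near 1400,
#' phosphodiester and C-O bands below 1250). Only bands inside the simulated
#' grid are rendered.
#'
#' @return Tibble with columns `center`, `fwhm`, `area`.
#' @export
background_band_table <- function() {
  tibble::tribble(
    ~center, ~fwhm, ~area,
    3400,    250,   60,
    2920,    60,    10,
    2850,    40,    4,
    1740,    90,    5,
    1400,    100,   8,
    1245,    80,    5,
    1088,    90,    6,
    1000,    80,    5
  )
}

#' Default class band profiles
#'
#' FM carries the four-band fingerprint including the disease-unique
#' 1565 cm-1 carboxylate band; LC carries three bands dominated by 1581; HC
#' carries the 1545 amide II band (4.1% of area) plus 1580/1639/1670 splitting
#' the remainder 70/10/20. `center_sd`/`rel_area_sd` columns carry the
#' reported between-patient dispersions and are used only when
#' [simulate_cohort()] is called with `jitter_bands = TRUE`.
#'
#' @param ... Passed to [class_profile()] (e.g. `noise_sd`).
#' @return Named list of `class_profile` objects (`FM`, `LC`, `HC`).
#' @export
default_class_profiles <- function(...) {
  fm <- tibble::tibble(
    center = c(1565, 1588, 1639, 1670), fwhm = 25,
    rel_area = c(0.361, 0.382, 0.047, 0.213),
    center_sd = c(3, 4, 5, 2), rel_area_sd = c(0.181, 0.156, 0.016, 0.075)
  )
  lc <- tibble::tibble(
    center = c(1581, 1635, 1670), fwhm = 25,
    rel_area = c(0.703, 0.099, 0.239),
    center_sd = c(2, 7, 2), rel_area_sd = c(0.089, 0.092, 0.053)
  )
  rem <- 1 - 0.041
  hc <- tibble::tibble(
    center = c(1545, 1580, 1639, 1670), fwhm = 25,
    rel_area = c(0.041, rem * 0.7, rem * 0.1, rem * 0.2),
    center_sd = c(2, 2, 7, 2), rel_area_sd = c(0.016, 0.089, 0.092, 0.053)
  )
  list(FM = class_profile("FM", fm, ...),
       LC = class_profile("LC", lc, ...),
       HC = class_profile("HC", hc, ...))
}

#' Nuisance loading of a profile on a grid
#'
#' @param profile A [class_profile()].
#' @param wavenumbers Grid to evaluate on.
#' @return Unit-norm numeric vector.
#' @export
nuisance_loading <- function(profile, wavenumbers) {
  v <- gaussian_band(wavenumbers, 1, profile$nuisance_center, profile$nuisance_fwhm)
  v / sqrt(sum(v^2))
}

# deterministic clean band sum (fingerprint + in-grid background)
render_clean <- function(profile, wavenumbers, bands = profile$bands) {
  rng <- range(wavenumbers)
  if (any(bands$center < rng[1] | bands$center > rng[2])) {
    bad <- bands$center[bands$center < rng[1] | bands$center > rng[2]]
    stop("band center(s) outside the simulation grid: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  y <- numeric(length(wavenumbers))
  for (k in seq_len(nrow(bands))) {
    y <- y + gaussian_band(wavenumbers,
                           gaussian_height(bands$rel_area[k] * profile$area_scale,
                                           bands$fwhm[k]),
                           bands$center[k], bands$fwhm[k])
  }
  bg <- profile$background_bands
  bg <- bg[bg$center >= rng[1] & bg$center <= rng[2], , drop = FALSE]
  for (k in seq_len(nrow(bg))) {
    y <- y + gaussian_band(wavenumbers, gaussian_height(bg$area[k], bg$fwhm[k]),
                           bg$center[k], bg$fwhm[k])
  }
  y
}

#' Render one synthetic spectrum
#'
#' With the default arguments all stochastic terms are zero and the result is
#' the deterministic band sum of the profile.
#'
#' @param profile A [class_profile()].
#' @param config A [sim_config()] defining the grid.
#' @param scale Global multiplicative amplitude.
#' @param slope Linear baseline slope (absorbance per cm-1, about the grid
#'   mean).
#' @param nuisance_score Score multiplying the profile's nuisance loading.
#' @param noise Either `NULL` (no noise), a single sd from which noise is
#'   drawn with the current RNG, or a pre-drawn vector of per-point noise.
#' @param bands Optional band table overriding `profile$bands` (used for
#'   per-sample jitter).
#' @param sample_id Sample identifier.
#' @param label Class label; defaults to the profile name.
#' @return One-row spectra tibble.
#' @export
render_spectrum <- function(profile, config = sim_config(), scale = 1, slope = 0,
                            nuisance_score = 0, noise = NULL, bands = NULL,
                            sample_id = profile$name, label = profile$name) {
  wn <- sim_grid(config)
  y <- scale * render_clean(profile, wn, bands %||% profile$bands)
  y <- y + slope * (wn - mean(wn))
  if (nuisance_score != 0) {
    y <- y + nuisance_score * nuisance_loading(profile, wn)
  }
  if (!is.null(noise)) {
    eps <- if (length(noise) == 1L) stats::rnorm(length(wn), 0, noise) else noise
    y <- y + eps
  }
  new_spectra(sample_id, label, matrix(y, nrow = 1), wn)
}

#' Simulate a labelled cohort of synthetic spectra
#'
#' Deterministic for a fixed `config$seed`: a per-sample substream seed is
#' drawn up front so the draws for sample i do not depend on how many other
#' samples are rendered.
#'
#' @param profiles Named list of [class_profile()]s (one class per entry).
#' @param config A [sim_config()].
#' @param jitter_bands If `TRUE`, each sample perturbs band centers and
#'   relative areas with the `center_sd`/`rel_area_sd` columns of the profile
#'   band table (the reported between-patient dispersions), renormalizing
#'   areas per sample.
#' @return A `sim_cohort` list with elements `spectra` (spectra tibble),
#'   `truth` (per-sample band parameters and draw values, for recovery tests)
#'   and `config`.
#' @export
simulate_cohort <- function(profiles = default_class_profiles()[c("FM", "LC")],
                            config = sim_config(), jitter_bands = FALSE) {
  wn <- sim_grid(config)
  n_total <- config$n_per_class * length(profiles)
  sub_seeds <- with_seed(config$seed,
                         sample.int(.Machine$integer.max, n_total))
  rows <- vector("list", n_total)
  truths <- vector("list", n_total)
  i <- 0L
  for (profile in profiles) {
    for (j in seq_len(config$n_per_class)) {
      i <- i + 1L
      sid <- sprintf("%s_%03d", profile$name, j)
      draws <- with_seed(sub_seeds[i], {
        bands <- profile$bands
        if (jitter_bands) {
          csd <- bands$center_sd %||% rep(0, nrow(bands))
          rsd <- bands$rel_area_sd %||% rep(0, nrow(bands))
          bands$center <- stats::rnorm(nrow(bands), bands$center, csd)
          bands$rel_area <- pmax(stats::rnorm(nrow(bands), bands$rel_area, rsd),
                                 1e-3)
          bands$rel_area <- bands$rel_area / sum(bands$rel_area)
        }
        list(
          bands = bands,
          scale = max(stats::rnorm(1, 1, profile$amplitude_cv), 0.2),
          slope = stats::rnorm(1, 0, profile$baseline_slope_sd),
          score = stats::rnorm(1, 0, profile$nuisance_sd),
          eps = stats::rnorm(length(wn), 0, profile$noise_sd)
        )
      })
      rows[[i]] <- render_spectrum(profile, config, scale = draws$scale,
                                   slope = draws$slope,
                                   nuisance_score = draws$score,
                                   noise = draws$eps, bands = draws$bands,
                                   sample_id = sid)
      truths[[i]] <- dplyr::mutate(
        draws$bands[, c("center", "fwhm", "rel_area")],
        sample_id = sid, label = profile$name,
        area = .data$rel_area * profile$area_scale,
        scale = draws$scale, slope = draws$slope,
        nuisance_score = draws$score, .before = 1
      )
    }
  }
  structure(list(spectra = dplyr::bind_rows(rows),
                 truth = dplyr::bind_rows(truths),
                 config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic FT-MIR cohort:", nrow(x$spectra), "spectra,",
      length(spectra_wavenumbers(x$spectra)), "grid points\n")
  print(table(x$spectra$label))
  invisible(x)
}

#' Write a cohort and its truth sidecar
#'
#' @param cohort A [simulate_cohort()] result.
#' @param path Spectra CSV path; the truth table goes to
#'   `<path base>_truth.csv`.
#' @return Paths, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write_spectra(cohort$spectra, path)
  truth_path <- sub("(\\.[^.]+)?$", "_truth.csv", path)
  readr::write_csv(cohort$truth, truth_path, progress = FALSE)
  invisible(c(spectra = path, truth = truth_path))
}

# evaluate an expression with a temporary RNG seed, restoring global state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
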