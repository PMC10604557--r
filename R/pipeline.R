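# End-to-end pipeline: simulate -> pretreat -> train/validate -> deconvolve ->
# compare, with a written report bundle and a manifest sufficient to re-run
# bit-identically.

#' Pipeline run configuration
#'
#' A single master seed fans out to the stage seeds by fixed offsets
#' (simulation uses `seed`, the stratified split `seed + 1`), so one knob
#' reproduces the whole run.
#'
#' @param sim A [sim_config()]; its seed is overridden by `seed`.
#' @param pp A [preprocess_config()].
#' @param model A [model_config()]; its split seed is overridden by `seed + 1`.
#' @param fit A [fit_config()].
#' @param classes Two class labels to simulate and discriminate.
#' @param alpha Significance level of the band comparison.
#' @param seed Master seed.
#' @param jitter_bands Passed to [simulate_cohort()].
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(), pp = preprocess_config(),
                       model = model_config(), fit = fit_config(),
                       classes = c("FM", "LC"), alpha = 0.05, seed = 1,
                       jitter_bands = FALSE) {
  stopifnot(inherits(sim, "sim_config"), inherits(pp, "preprocess_config"),
            inherits(model, "model_config"), inherits(fit, "fit_config"),
            length(classes) == 2, alpha > 0, alpha < 1)
  sim$seed <- as.integer(seed)
  model$split_seed <- as.integer(seed + 1)
  structure(list(sim = sim, pp = pp, model = model, fit = fit,
                 classes = classes, alpha = alpha, seed = as.integer(seed),
                 jitter_bands = isTRUE(jitter_bands)),
            class = "run_config")
}

#' Run the full fingerprinting pipeline
#'
#' Simulates a two-class cohort, splits it stratified 80/20, fits the
#' OSC-PLS-DA chain on the training set, runs leave-one-out cross-validation
#' and external validation with ROC curves, deconvolves both classes and
#' compares their band tables. All tables are written as CSV under `out_dir`
#' together with a JSON manifest and a plain-text log; any stage error aborts
#' with the stage name while earlier outputs are preserved.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return A `fingerprint_run` bundle (all results plus file paths),
#'   invisibly printable via [report_summary()].
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("specfinger_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    say("stage %s: start", name)
    out <- tryCatch(expr, error = function(e) {
      writeLines(log_lines, file.path(out_dir, "log.txt"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    say("stage %s: done", name)
    out
  }
  paths <- list()
  emit <- function(name, df) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(df, p, progress = FALSE)
    paths[[name]] <<- p
    p
  }

  cohort <- stage("simulate", {
    profiles <- default_class_profiles()[config$classes]
    simulate_cohort(profiles, config$sim, jitter_bands = config$jitter_bands)
  })
  emit("cohort", cohort$spectra)
  emit("cohort_truth", cohort$truth)

  split <- stage("split", split_cohort(cohort$spectra,
                                       config$model$split_fraction,
                                       config$model$split_seed))
  say("split: %d training, %d validation", nrow(split$train),
      nrow(split$validation))

  model <- stage("train", plsda(split$train, config$model, config$pp))
  emit("regression_vector", tidy(model))
  emit("scores", predict(model))

  cv <- stage("cross_validate",
              cross_validate(split$train, config$model, config$pp))
  emit("cv_predictions", cv$predictions)
  emit("cv_metrics", glance(cv))
  emit("roc_cv", tibble::as_tibble(cv$roc))

  ev <- stage("external_validate", external_validate(model, split$validation))
  emit("ev_predictions", ev$predictions)
  emit("ev_metrics", glance(ev))
  emit("roc_ev", tibble::as_tibble(ev$roc))

  bands <- stage("deconvolve",
                 deconvolve(cohort$spectra, config$fit, config$pp))
  for (cl in config$classes) {
    emit(paste0("deconv_", cl), bands[bands$label == cl, ])
  }
  band_summary <- stage("summarize_bands",
                        summarize_bands(bands, config$fit$merge_distance,
                                        min_frac = 0.5))
  emit("band_summary", band_summary)

  comparison <- stage("compare", compare_band_tables(
    bands[bands$label == config$classes[1], ],
    bands[bands$label == config$classes[2], ],
    alpha = config$alpha,
    merge_distance = config$fit$merge_distance
  ))
  emit("band_comparison", comparison)

  manifest <- list(
    package = "specfinger",
    version = as.character(utils::packageVersion("specfinger")),
    seed = config$seed,
    config = config,
    n_train = nrow(split$train),
    n_validation = nrow(split$validation),
    files = vapply(paths, basename, "")
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  writeLines(log_lines, file.path(out_dir, "log.txt"))

  structure(list(
    config = config, out_dir = out_dir, paths = paths,
    cohort = cohort, split = split, model = model, cv = cv, ev = ev,
    bands = bands, band_summary = band_summary, comparison = comparison,
    manifest = manifest
  ), class = "fingerprint_run")
}

#' One-page text summary of a pipeline run
#'
#' Reports the figures of merit in the conventional order (SECV/SEP, R2,
#' sensitivity, specificity, accuracy) plus ROC areas and the band-comparison
#' highlights. Every number is read from the bundle; nothing is recomputed.
#'
#' @param bundle A [run_pipeline()] result.
#' @return Character vector of report lines, invisibly; printed as a side
#'   effect.
#' @export
report_summary <- function(bundle) {
  stopifnot(inherits(bundle, "fingerprint_run"))
  cv <- glance(bundle$cv)
  has_ev <- nrow(bundle$split$validation) > 0
  lines <- c(
    "== Metabolic fingerprinting run ==",
    sprintf("seed %d | %d + %d spectra (%s vs %s)",
            bundle$config$seed, sum(bundle$cohort$spectra$label ==
                                      bundle$config$classes[1]),
            sum(bundle$cohort$spectra$label == bundle$config$classes[2]),
            bundle$config$classes[1], bundle$config$classes[2]),
    sprintf("model: %d OSC + %d LV, region %g-%g cm-1",
            bundle$config$model$n_osc, bundle$config$model$n_lv,
            bundle$config$pp$region[1], bundle$config$pp$region[2]),
    "-- internal cross-validation (leave-one-out) --",
    sprintf("SECV %.3f | Rcv %.3f | misclassified %d/%d | AUC %.3f",
            cv$secv, cv$rcv, cv$misclassifications, cv$n, cv$auc)
  )
  if (has_ev) {
    ev <- glance(bundle$ev)
    lines <- c(lines,
      "-- external validation --",
      sprintf("SEP %.3f | R2 %.3f | sensitivity %.0f%% | specificity %.0f%% | accuracy %.0f%% | AUC %.3f",
              ev$sep, ev$r2, ev$sensitivity, ev$specificity, ev$accuracy,
              ev$auc))
  } else {
    lines <- c(lines, "-- external validation: absent (no validation set) --")
  }
  uniq <- bundle$comparison[!is.na(bundle$comparison$unique_to), ]
  lines <- c(lines, "-- band comparison --")
  if (nrow(uniq)) {
    lines <- c(lines, sprintf("unique band: %.0f cm-1 only in %s",
                              ifelse(is.na(uniq$center_a), uniq$center_b,
                                     uniq$center_a),
                              uniq$unique_to))
  }
  sig <- bundle$comparison[!is.na(bundle$comparison$significant_area) &
                             bundle$comparison$significant_area, ]
  if (nrow(sig)) {
    lines <- c(lines, sprintf(
      "area differs at %.0f/%.0f cm-1: %.1f%% vs %.1f%% (p = %.2g)",
      sig$center_a, sig$center_b, sig$pct_area_a, sig$pct_area_b, sig$p_area))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.fingerprint_run <- function(x, ...) {
  report_summary(x)
  invisible(x)
}
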