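# Model assessment: stratified splitting, leave-one-out internal
# cross-validation (refitting the whole chain per fold), external validation
# figures of merit, and ROC/AUC.

#' Stratified random train/validation split
#'
#' Per class, `round(fraction * n_class)` samples go to training; the split is
#' deterministic for a fixed seed and the two sets are disjoint.
#'
#' @inheritParams spectra_wavenumbers
#' @param fraction Training share.
#' @param seed RNG seed.
#' @return List with spectra tibbles `train` and `validation`.
#' @export
split_cohort <- function(data, fraction = 0.8, seed = 1) {
  stopifnot(fraction > 0, fraction < 1)
  counts <- table(data$label)
  if (any(counts < 2)) {
    stop("every class needs at least 2 samples to split", call. = FALSE)
  }
  idx_train <- with_seed(seed, {
    unlist(lapply(names(counts), function(cl) {
      rows <- which(data$label == cl)
      sample(rows, round(fraction * length(rows)))
    }))
  })
  idx_train <- sort(idx_train)
  list(train = data[idx_train, ], validation = data[-idx_train, ])
}

#' Leave-one-out cross-validation of the discriminant chain
#'
#' Each sample is predicted by a chain (centering means, OSC, PLS) re-fitted
#' on the remaining n - 1 samples, so no fold sees its held-out sample at any
#' stage. The per-sample operations of the pretreatment (normalization and
#' derivative filters) are sample-independent and are computed once.
#'
#' @inheritParams plsda
#' @return A `plsda_cv` object: `predictions` tibble, `secv`
#'   (root-mean-square cross-validated residual, denominator n), `rcv`
#'   (Pearson correlation of cross-validated predictions with the class
#'   codes), `misclassifications`, and `auc` (cross-validated ROC area with
#'   `positive_class` positive).
#' @export
cross_validate <- function(data, config = model_config(),
                           pp = preprocess_config()) {
  n <- nrow(data)
  if (n < 3) stop("leave-one-out needs at least 3 samples", call. = FALSE)
  y <- label_code(data$label)
  z <- pretreat_transform(data, pp)   # per-sample ops only, no centering
  yhat <- vapply(seq_len(n), function(i) {
    mc <- mean_center(z$x[-i, , drop = FALSE])
    x_tr <- mc$x
    osc <- NULL
    if (config$n_osc > 0) {
      osc <- osc_fit(x_tr, y[-i], config$n_osc)
      x_tr <- osc$x_corrected
    }
    ybar <- mean(y[-i])
    pls <- pls_fit(x_tr, y[-i] - ybar, config$n_lv)
    x_new <- z$x[i, , drop = FALSE] - rep(mc$means, each = 1)
    if (!is.null(osc)) x_new <- osc_apply(osc, x_new)
    ybar + drop(x_new %*% pls$b)
  }, numeric(1))
  class_pred <- ifelse(yhat < config$class_threshold, "FM", "LC")
  preds <- tibble::tibble(sample_id = data$sample_id, label = data$label,
                          y_obs = y, y_score = yhat, class_pred = class_pred)
  roc <- roc_curve(positive_score(yhat, config$positive_class), data$label,
                   positive = config$positive_class)
  structure(list(
    predictions = preds,
    secv = sqrt(mean((yhat - y)^2)),
    rcv = stats::cor(yhat, y),
    misclassifications = sum(class_pred != data$label),
    auc = attr(roc, "auc"),
    roc = roc,
    config = config
  ), class = "plsda_cv")
}

#' @method glance plsda_cv
#' @export
glance.plsda_cv <- function(x, ...) {
  tibble::tibble(n = nrow(x$predictions), secv = x$secv, rcv = x$rcv,
                 misclassifications = x$misclassifications, auc = x$auc)
}

#' @export
print.plsda_cv <- function(x, ...) {
  cat(sprintf(
    "Leave-one-out CV: n = %d, SECV = %.3f, Rcv = %.3f, misclassified = %d, AUC = %.3f\n",
    nrow(x$predictions), x$secv, x$rcv, x$misclassifications, x$auc))
  invisible(x)
}

# orient a class-code score so that larger means more like the positive class
positive_score <- function(y_score, positive_class) {
  if (positive_class == "FM") -y_score else y_score
}

#' External validation of a fitted discriminant chain
#'
#' @param object A [plsda()] model fitted on training data only.
#' @param newdata Held-out spectra tibble.
#' @return A `plsda_ev` object: `predictions`, `sep` (root-mean-square
#'   prediction residual), `r2` (squared Pearson correlation of predictions
#'   and class codes), `sensitivity`/`specificity`/`accuracy` (percent, with
#'   the configured positive class), `confusion` counts and `auc`.
#' @export
external_validate <- function(object, newdata) {
  if (!nrow(newdata)) stop("validation set is empty", call. = FALSE)
  preds <- predict(object, newdata)
  pos <- object$config$positive_class
  tp <- sum(preds$label == pos & preds$class_pred == pos)
  fn <- sum(preds$label == pos & preds$class_pred != pos)
  tn <- sum(preds$label != pos & preds$class_pred != pos)
  fp <- sum(preds$label != pos & preds$class_pred == pos)
  roc <- roc_curve(positive_score(preds$y_score, pos), preds$label,
                   positive = pos)
  structure(list(
    predictions = preds,
    sep = sqrt(mean((preds$y_score - preds$y_obs)^2)),
    r2 = if (stats::sd(preds$y_score) == 0) NA_real_ else
      stats::cor(preds$y_score, preds$y_obs)^2,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy = 100 * (tp + tn) / nrow(preds),
    confusion = tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn),
    auc = attr(roc, "auc"),
    roc = roc,
    positive_class = pos
  ), class = "plsda_ev")
}

#' @method glance plsda_ev
#' @export
glance.plsda_ev <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n = nrow(x$predictions), sep = x$sep, r2 = x$r2,
                   sensitivity = x$sensitivity, specificity = x$specificity,
                   accuracy = x$accuracy, auc = x$auc),
    x$confusion
  )
}

#' @export
print.plsda_ev <- function(x, ...) {
  cat(sprintf(
    "External validation: n = %d, SEP = %.3f, R2 = %.3f, sens = %.0f%%, spec = %.0f%%, acc = %.0f%%, AUC = %.3f\n",
    nrow(x$predictions), x$sep, x$r2, x$sensitivity, x$specificity,
    x$accuracy, x$auc))
  invisible(x)
}

#' Empirical ROC curve and AUC
#'
#' Sweeps thresholds over the observed scores (larger score = more positive);
#' the trapezoid-rule area equals the pairwise concordance (Mann-Whitney)
#' statistic with ties counted one half.
#'
#' @param score Numeric scores.
#' @param label Class labels (both classes must be present).
#' @param positive Label counted as positive.
#' @return A `roc_curve` tibble with `threshold`, `fpr`, `tpr`, ordered along
#'   the sweep, and an `auc` attribute.
#' @export
roc_curve <- function(score, label, positive) {
  is_pos <- label == positive
  if (!any(is_pos) || all(is_pos)) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(score[is_pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(score[!is_pos] >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  out <- tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr)
  class(out) <- c("roc_curve", class(out))
  attr(out, "auc") <- auc
  out
}

#' Area under a ROC curve
#'
#' @param roc A [roc_curve()] result.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  attr(roc, "auc")
}
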