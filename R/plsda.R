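# NIPALS PLS regression on the dummy-coded class response, and the high-level
# discriminant model combining pretreatment, OSC and PLS.

#' Model configuration for the discriminant chain
#'
#' @param n_osc Orthogonal signal correction components (default 1).
#' @param n_lv PLS latent variables (default 1).
#' @param class_threshold Decision midpoint on the predicted response; with
#'   the FM = 1 / LC = 2 coding the midpoint is 1.5. Ties go to LC.
#' @param positive_class Label treated as positive for sensitivity and ROC.
#' @param split_fraction Training share of a stratified random split.
#' @param split_seed Seed of the stratified split.
#' @return A `model_config` list.
#' @export
model_config <- function(n_osc = 1, n_lv = 1, class_threshold = 1.5,
                         positive_class = "FM", split_fraction = 0.8,
                         split_seed = 1) {
  stopifnot(n_osc >= 0, n_lv >= 1,
            split_fraction > 0, split_fraction < 1)
  structure(list(n_osc = as.integer(n_osc), n_lv = as.integer(n_lv),
                 class_threshold = class_threshold,
                 positive_class = positive_class,
                 split_fraction = split_fraction,
                 split_seed = as.integer(split_seed)),
            class = "model_config")
}

#' NIPALS PLS fit (univariate response)
#'
#' @param x Centered (and OSC-corrected) matrix.
#' @param y Centered response vector.
#' @param n_lv Number of latent variables.
#' @return A `pls` object: `w` (weights), `p` (x-loadings), `q` (y-loadings),
#'   `scores`, regression vector `b = W (P'W)^-1 q`, and `r2x` (fraction of
#'   X sum of squares captured per LV).
#' @export
pls_fit <- function(x, y, n_lv = 1) {
  x <- as.matrix(x)
  dimnames(x) <- NULL
  y <- unname(y)
  if (sum(abs(y)) == 0) stop("response is constant", call. = FALSE)
  if (sum(x^2) == 0) stop("predictor matrix has zero variance", call. = FALSE)
  totss <- sum(x^2)
  w_mat <- p_mat <- matrix(0, ncol(x), n_lv)
  t_mat <- matrix(0, nrow(x), n_lv)
  q_vec <- r2x <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(x, y))
    wn <- sqrt(sum(w^2))
    if (wn < .Machine$double.eps * ncol(x)) {
      stop("X-y covariance vanished at latent variable ", a, call. = FALSE)
    }
    w <- w / wn
    tt <- drop(x %*% w)
    q <- sum(tt * y) / sum(tt^2)
    p <- drop(crossprod(x, tt)) / sum(tt^2)
    x <- x - tcrossprod(tt, p)
    y <- y - tt * q
    w_mat[, a] <- w
    p_mat[, a] <- p
    t_mat[, a] <- tt
    q_vec[a] <- q
    r2x[a] <- sum(tt^2 * sum(p^2)) / totss
  }
  b <- drop(w_mat %*% solve(crossprod(p_mat, w_mat), q_vec))
  structure(list(w = w_mat, p = p_mat, q = q_vec, scores = t_mat, b = b,
                 r2x = r2x, n_lv = n_lv),
            class = "pls")
}

#' Fit the OSC-PLS-DA discriminant chain
#'
#' Pretreats the spectra (normalize, smooth, second derivative, region, mean
#' center), removes `n_osc` orthogonal components, and fits a NIPALS PLS
#' regression of the spectra onto the FM = 1 / LC = 2 dummy response.
#'
#' @param data Spectra tibble with exactly two classes.
#' @param config A [model_config()].
#' @param pp A [preprocess_config()].
#' @return A `plsda` object.
#' @export
plsda <- function(data, config = model_config(), pp = preprocess_config()) {
  y <- label_code(data$label)
  if (length(unique(y)) != 2) {
    stop("plsda expects exactly two classes in the training data", call. = FALSE)
  }
  pt <- pretreat(data, pp)
  x <- pt$x
  osc <- NULL
  if (config$n_osc > 0) {
    osc <- osc_fit(x, y, config$n_osc)
    x <- osc$x_corrected
  }
  ybar <- mean(y)
  pls <- pls_fit(x, y - ybar, config$n_lv)
  structure(list(pretreatment = pt, osc = osc, pls = pls, ybar = ybar,
                 config = config, n = nrow(x),
                 fitted = unname(ybar + drop(x %*% pls$b))),
            class = "plsda")
}

# pretreated + OSC-corrected matrix for new spectra
chain_transform <- function(object, data) {
  x <- pretreat_apply(object$pretreatment, data)
  if (!is.null(object$osc)) x <- osc_apply(object$osc, x)
  x
}

#' Predict class membership for new spectra
#'
#' @param object A [plsda()] model.
#' @param newdata Spectra tibble; the training set when `NULL`.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `label`, `y_obs` (dummy code, `NA` for
#'   unlabelled data), continuous `y_score`, and `class_pred` (`FM` below the
#'   threshold, `LC` at or above it).
#' @export
predict.plsda <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    scores <- object$fitted
    sid <- object$pretreatment$sample_id
    lab <- object$pretreatment$label
  } else {
    x <- chain_transform(object, newdata)
    scores <- unname(object$ybar + drop(x %*% object$pls$b))
    sid <- newdata$sample_id
    lab <- newdata$label
  }
  tibble::tibble(
    sample_id = sid, label = lab,
    y_obs = if (is.null(lab)) NA_real_ else label_code(lab),
    y_score = scores,
    class_pred = ifelse(scores < object$config$class_threshold, "FM", "LC")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Regression vector of a fitted discriminant model
#'
#' @param x A [plsda()] model.
#' @param ... Unused.
#' @return Tibble with `wavenumber` and `coefficient` (the spectral-space
#'   regression vector b mapping a pretreated spectrum to a class code).
#' @method tidy plsda
#' @export
tidy.plsda <- function(x, ...) {
  tibble::tibble(wavenumber = x$pretreatment$wavenumbers,
                 coefficient = x$pls$b)
}

#' One-row model summary
#'
#' @param x A [plsda()] model.
#' @param ... Unused.
#' @return Tibble with the sample count, component counts, percentage of
#'   X variance explained by the latent variables and removed by OSC, and the
#'   training RMSE.
#' @method glance plsda
#' @export
glance.plsda <- function(x, ...) {
  y <- label_code(x$pretreatment$label)
  tibble::tibble(
    n = x$n,
    n_osc = x$config$n_osc,
    n_lv = x$config$n_lv,
    x_variance_explained_pct = 100 * sum(x$pls$r2x),
    osc_removed_pct = if (is.null(x$osc)) 0 else 100 * sum(x$osc$removed),
    rmse = sqrt(mean((x$fitted - y)^2))
  )
}

#' @export
print.plsda <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "OSC-PLS-DA model: n = %d, %d OSC + %d LV, LV X-variance %.1f%%, training RMSE %.4f\n",
    g$n, g$n_osc, g$n_lv, g$x_variance_explained_pct, g$rmse))
  invisible(x)
}
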