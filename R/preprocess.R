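# Spectral pretreatment chain: unit-vector normalization, Savitzky-Golay
# smoothing, Savitzky-Golay second derivative, region selection, mean
# centering (training means only). The order follows the source protocol.

#' Preprocessing configuration
#'
#' @param norm `"unit"` (Euclidean-norm normalization over the full recorded
#'   range, the standard correction for ATR film-thickness variation) or
#'   `"none"`.
#' @param smooth_window,smooth_polyorder Savitzky-Golay smoothing filter
#'   (default 5 points, order 2).
#' @param deriv_window,deriv_polyorder Savitzky-Golay derivative filter
#'   (default 7 points, order 2).
#' @param deriv_order Derivative order; the protocol fixes 2.
#' @param region Wavenumber interval `c(lo, hi)` retained for modelling
#'   (closed; default the 1528-1624 cm-1 discriminating window), or `NULL`
#'   for the full grid.
#' @param mean_center Subtract training column means before modelling.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(norm = c("unit", "none"), smooth_window = 5,
                              smooth_polyorder = 2, deriv_window = 7,
                              deriv_polyorder = 2, deriv_order = 2,
                              region = c(1528, 1624), mean_center = TRUE) {
  norm <- match.arg(norm)
  check_window <- function(w, p, what) {
    if (w %% 2 != 1 || w <= p) {
      stop(what, " window must be odd and larger than its polynomial order",
           call. = FALSE)
    }
  }
  check_window(smooth_window, smooth_polyorder, "smoothing")
  check_window(deriv_window, deriv_polyorder, "derivative")
  if (deriv_order != 2) stop("deriv_order is fixed at 2", call. = FALSE)
  if (!is.null(region) && region[1] >= region[2]) {
    stop("region must satisfy lo < hi", call. = FALSE)
  }
  structure(list(norm = norm, smooth_window = smooth_window,
                 smooth_polyorder = smooth_polyorder,
                 deriv_window = deriv_window,
                 deriv_polyorder = deriv_polyorder, deriv_order = deriv_order,
                 region = region, mean_center = isTRUE(mean_center)),
            class = "preprocess_config")
}

#' Savitzky-Golay convolution coefficients
#'
#' Least-squares local polynomial filter weights. For `window = 7`,
#' `polyorder = 2`, `deriv = 2` these are the classic
#' `(5, 0, -3, -4, -3, 0, 5) / 42` second-derivative weights (per unit step
#' squared).
#'
#' @param window Odd window length (points).
#' @param polyorder Local polynomial order (< window).
#' @param deriv Derivative order (<= polyorder).
#' @return Numeric vector of `window` weights.
#' @export
sg_coefficients <- function(window, polyorder, deriv = 0) {
  stopifnot(window %% 2 == 1, window > polyorder, deriv <= polyorder)
  m <- (window - 1) / 2
  a <- outer(-m:m, 0:polyorder, `^`)
  cmat <- solve(crossprod(a), t(a))
  factorial(deriv) * cmat[deriv + 1, ]
}

#' Savitzky-Golay filter of a numeric vector
#'
#' Interior points use the convolution weights; the first/last half-window is
#' handled by fitting the terminal window's polynomial and evaluating its
#' derivative at the edge offsets, so the output grid equals the input grid.
#' Derivatives are scaled by the grid step, giving units of signal per
#' (cm-1)^deriv; the second derivative is invariant to grid direction.
#'
#' @param x Numeric signal (one spectrum).
#' @param window,polyorder,deriv As in [sg_coefficients()].
#' @param delta Absolute grid spacing.
#' @return Filtered vector, same length as `x`.
#' @export
sg_filter <- function(x, window, polyorder, deriv = 0, delta = 1) {
  n <- length(x)
  if (n < window) stop("signal shorter than the filter window", call. = FALSE)
  w <- sg_coefficients(window, polyorder, deriv)
  m <- (window - 1) / 2
  out <- as.numeric(stats::filter(x, rev(w), sides = 2))
  # edge handling: polynomial fit over each terminal window, evaluated at the
  # interior offsets
  offs <- -m:m
  a <- outer(offs, 0:polyorder, `^`)
  cmat <- solve(crossprod(a), t(a))
  poly_deriv <- function(coefs, t) {
    s <- 0
    for (k in deriv:polyorder) {
      s <- s + coefs[k + 1] * factorial(k) / factorial(k - deriv) * t^(k - deriv)
    }
    s
  }
  cl <- cmat %*% x[1:window]
  cr <- cmat %*% x[(n - window + 1):n]
  for (i in seq_len(m)) {
    out[i] <- poly_deriv(cl, offs[i])
    out[n - m + i] <- poly_deriv(cr, offs[window - m + i])
  }
  out / delta^deriv
}

#' Apply a Savitzky-Golay filter to every spectrum of a dataset
#'
#' @inheritParams spectra_wavenumbers
#' @inheritParams sg_filter
#' @return Spectra tibble on the same grid.
#' @export
sg_transform <- function(data, window, polyorder, deriv = 0) {
  validate_spectra(data, min_points = window)
  wn <- spectra_wavenumbers(data)
  delta <- abs(wn[2] - wn[1])
  x <- spectra_matrix(data)
  out <- t(apply(x, 1, sg_filter, window = window, polyorder = polyorder,
                 deriv = deriv, delta = delta))
  new_spectra(data$sample_id, data$label, out, wn)
}

#' Unit-vector normalization of each spectrum
#'
#' Divides each spectrum by its Euclidean norm so downstream results are
#' invariant to per-sample positive scaling.
#'
#' @inheritParams spectra_wavenumbers
#' @param method `"unit"` or `"none"`.
#' @return Spectra tibble.
#' @export
normalize_spectra <- function(data, method = c("unit", "none")) {
  method <- match.arg(method)
  if (method == "none") return(data)
  validate_spectra(data)
  x <- spectra_matrix(data)
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) {
    stop("cannot normalize all-zero spectrum: ",
         paste(data$sample_id[nrm == 0], collapse = ", "), call. = FALSE)
  }
  new_spectra(data$sample_id, data$label, x / nrm, spectra_wavenumbers(data))
}

#' Restrict to a wavenumber region
#'
#' Keeps grid points with `lo <= wavenumber <= hi` (closed interval),
#' preserving column order. Works on a spectra tibble or on a two-column
#' `wavenumber`/value tibble.
#'
#' @param data Spectra tibble or tibble with a `wavenumber` column.
#' @param lo,hi Region bounds (cm-1).
#' @return Same kind of object, restricted.
#' @export
select_region <- function(data, lo, hi) {
  stopifnot(lo < hi)
  if ("wavenumber" %in% names(data)) {
    out <- data[data$wavenumber >= lo & data$wavenumber <= hi, , drop = FALSE]
    if (!nrow(out)) stop("region does not overlap the grid", call. = FALSE)
    return(out)
  }
  wn <- spectra_wavenumbers(data)
  keep <- wn >= lo & wn <= hi
  if (!any(keep)) stop("region does not overlap the grid", call. = FALSE)
  data[, c(TRUE, TRUE, keep)]
}

#' Mean-center the columns of a matrix
#'
#' @param x Numeric matrix (samples x variables).
#' @param means Column means to subtract; computed from `x` when `NULL`
#'   (training mode). Supply training means to center held-out samples.
#' @return List with the centered matrix `x` and the `means` used.
#' @export
mean_center <- function(x, means = NULL) {
  if (is.null(means)) {
    if (nrow(x) < 2) stop("mean centering needs at least 2 samples", call. = FALSE)
    means <- colMeans(x)
  }
  list(x = sweep(x, 2, means), means = means)
}

#' Fit the pretreatment chain on training spectra
#'
#' Runs normalize -> smooth -> second derivative -> region -> mean center and
#' stores the fitted state (training column means) so held-out samples can be
#' transformed identically.
#'
#' @inheritParams spectra_wavenumbers
#' @param config A [preprocess_config()].
#' @return A `pretreatment` object with elements `x` (centered matrix),
#'   `means`, `wavenumbers`, `sample_id`, `label`, `config`.
#' @export
pretreat <- function(data, config = preprocess_config()) {
  z <- pretreat_transform(data, config)
  if (config$mean_center) {
    mc <- mean_center(z$x)
    z$x <- mc$x
    z$means <- mc$means
  } else {
    z$means <- rep(0, ncol(z$x))
  }
  structure(c(z, list(config = config)), class = "pretreatment")
}

# per-sample part of the chain (label-free, sample-independent)
pretreat_transform <- function(data, config) {
  data <- normalize_spectra(data, config$norm)
  data <- sg_transform(data, config$smooth_window, config$smooth_polyorder, 0)
  data <- sg_transform(data, config$deriv_window, config$deriv_polyorder,
                       config$deriv_order)
  if (!is.null(config$region)) {
    data <- select_region(data, config$region[1], config$region[2])
  }
  list(x = spectra_matrix(data), wavenumbers = spectra_wavenumbers(data),
       sample_id = data$sample_id, label = data$label)
}

#' Transform new spectra with a fitted pretreatment
#'
#' @param object A [pretreat()] result.
#' @param data New spectra tibble on the same grid.
#' @return Centered matrix (using the stored training means).
#' @export
pretreat_apply <- function(object, data) {
  z <- pretreat_transform(data, object$config)
  if (!isTRUE(all.equal(z$wavenumbers, object$wavenumbers))) {
    stop("grid mismatch between new spectra and fitted pretreatment",
         call. = FALSE)
  }
  sweep(z$x, 2, object$means)
}
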