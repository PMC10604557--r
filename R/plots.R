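# ggplot2 graphics for spectra, ROC curves, model scores and band fits.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot spectra colored by class
#'
#' @inheritParams spectra_wavenumbers
#' @param n Maximum number of spectra drawn per class.
#' @return A ggplot.
#' @export
plot_spectra <- function(data, n = 10) {
  keep <- unlist(lapply(split(seq_len(nrow(data)), data$label),
                        utils::head, n))
  long <- tidyr::pivot_longer(data[keep, ],
                              cols = -c("sample_id", "label"),
                              names_to = "wavenumber",
                              values_to = "absorbance")
  long$wavenumber <- as.numeric(long$wavenumber)
  ggplot2::ggplot(long, ggplot2::aes(.data$wavenumber, .data$absorbance,
                                     group = .data$sample_id,
                                     colour = .data$label)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "wavenumber (cm⁻¹)", y = "absorbance",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' @method autoplot plsda
#' @export
autoplot.plsda <- function(object, ...) {
  df <- tibble::tibble(sample = seq_len(object$n),
                       score = object$pls$scores[, 1],
                       label = object$pretreatment$label)
  ggplot2::ggplot(df, ggplot2::aes(.data$sample, .data$score,
                                   colour = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "sample", y = "LV1 score", colour = "class",
                  title = "OSC-PLS-DA score plot") +
    ggplot2::theme_minimal()
}

#' @method autoplot band_fit
#' @export
autoplot.band_fit <- function(object, ...) {
  sig <- object$signal
  df <- tibble::tibble(wavenumber = sig$wavenumber, observed = sig$signal,
                       fitted = object$fitted)
  bands <- object$bands
  comp <- dplyr::bind_rows(lapply(seq_len(nrow(bands)), function(k) {
    tibble::tibble(
      wavenumber = sig$wavenumber,
      value = neg_d2_band(sig$wavenumber, bands$amplitude[k],
                          bands$center[k], bands$fwhm[k]),
      band = sprintf("%.0f", bands$center[k])
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed), colour = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red",
                       linetype = 2) +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(y = .data$value, colour = .data$band)) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "wavenumber (cm⁻¹)",
                  y = "inverted second derivative", colour = "band") +
    ggplot2::theme_minimal()
}
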