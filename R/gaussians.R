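# FWHM-parameterized Gaussian band profiles and their derivative-domain images.
# Throughout the package a band is g(x) = h * exp(-4 ln2 (x - c)^2 / w^2) with
# w the full width at half maximum, so area = h * w * sqrt(pi / (4 ln2)).

FWHM_LOG <- 4 * log(2)

#' Evaluate an FWHM-parameterized Gaussian band
#'
#' @param x Numeric vector of wavenumbers (cm-1).
#' @param height Peak height (absorbance units).
#' @param center Band center (cm-1).
#' @param fwhm Full width at half maximum (cm-1).
#' @return Numeric vector of band absorbance at `x`.
#' @examples
#' gaussian_band(1590:1610, height = 1, center = 1600, fwhm = 20)
#' @export
gaussian_band <- function(x, height, center, fwhm) {
  height * exp(-FWHM_LOG * (x - center)^2 / fwhm^2)
}

#' Analytic area of an FWHM-parameterized Gaussian band
#'
#' @inheritParams gaussian_band
#' @return `height * fwhm * sqrt(pi / (4 log(2)))`.
#' @export
gaussian_area <- function(height, fwhm) {
  height * fwhm * sqrt(pi / FWHM_LOG)
}

#' Peak height of a Gaussian band with a given area
#'
#' @param area Integrated band area (absorbance x cm-1).
#' @inheritParams gaussian_band
#' @return Peak height.
#' @export
gaussian_height <- function(area, fwhm) {
  area / (fwhm * sqrt(pi / FWHM_LOG))
}

# Negative second derivative of the band, parameterized by its own peak
# amplitude d = h * 8 ln2 / w^2 (the height of the central lobe in
# inverted-second-derivative units). Used as the deconvolution model.
neg_d2_band <- function(x, amp, center, fwhm) {
  a <- FWHM_LOG * (x - center)^2 / fwhm^2
  amp * (1 - 2 * a) * exp(-a)
}

# FWHM of the central lobe of -g'' relative to the FWHM of g itself:
# solve (1 - u^2) exp(-u^2 / 2) = 1/2 for u, lobe width = 2 u sigma.
LOBE_FWHM_FACTOR <- local({
  u <- stats::uniroot(function(u) (1 - u^2) * exp(-u^2 / 2) - 0.5, c(0.1, 1))$root
  2 * u / (2 * sqrt(2 * log(2)))
})
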