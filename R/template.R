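#' Vitamin-A1 visual pigment absorbance template
#'
#' Evaluates the alpha-band of a vitamin-A1 visual pigment absorbance
#' spectrum for a given wavelength of peak sensitivity (lambda_max), using
#' the modified log-normal form of Stavenga-style templates: with
#' `x = log10(lambda / lambda_max)`,
#'
#'   `S(x) = exp(-a0 * x^2 * (1 + a1 * x + a2 * x^2))`
#'
#' with alpha-band coefficients `a0 = 380`, `a1 = 6.09`,
#' `a2 = 3 * a1^2 / 8`. Because the curve depends on wavelength only
#' through the ratio `lambda / lambda_max`, the template is
#' shape-invariant on a log-wavelength axis and is exactly 1 at
#' `lambda = lambda_max`.
#'
#' The closed form is a fit to measured pigment spectra and is only
#' trustworthy near the alpha band; outside `lambda / lambda_max` in
#' `[0.58, 1.30]` the template is set to 0 and a warning is raised. The
#' beta band (the secondary UV absorbance peak of A1 pigments) is not
#' included: within the 400-700 nm instrument window of this package it
#' contributes little for violet-peaking pigments, and the single-curve
#' alpha-band fit is what the downstream attenuation summaries use.
#'
#' @param lambda_max_nm Peak sensitivity wavelength in nm, within
#'   \[330, 650\].
#' @param grid Wavelength grid in nm, within \[300, 800\].
#' @return A [spectrum()] of kind `"sensitivity"`, peak-normalised.
#' @export
#' @examples
#' tmpl <- a1_template(415, spectral_grid(350, 520, 0.5))
#' max(tmpl$value)  # 1 at 415 nm
a1_template <- function(lambda_max_nm, grid = default_model_grid()) {
  stopifnot(length(lambda_max_nm) == 1, is.finite(lambda_max_nm))
  if (lambda_max_nm < 330 || lambda_max_nm > 650) {
    stop("lambda_max_nm = ", lambda_max_nm,
         " nm outside the supported range [330, 650] nm")
  }
  grid <- as.numeric(grid)
  if (min(grid) < 300 || max(grid) > 800) {
    stop("template grid must lie within [300, 800] nm")
  }
  a0 <- 380
  a1 <- 6.09
  a2 <- 3 * a1^2 / 8
  ratio <- grid / lambda_max_nm
  x <- log10(ratio)
  v <- exp(-a0 * x^2 * (1 + a1 * x + a2 * x^2))
  out_of_band <- ratio < 0.58 | ratio > 1.30
  if (any(out_of_band)) {
    warning(sum(out_of_band),
            " grid point(s) outside the template validity window ",
            "(lambda/lambda_max in [0.58, 1.30]); set to 0")
    v[out_of_band] <- 0
  }
  spectrum(grid, v, "sensitivity")
}
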