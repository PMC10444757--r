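#' Effective transmittance of a partially dispersed chromatophore
#'
#' Chromatophore pigment granules aggregate into a small central mass
#' (leaving most of the cell footprint clear) or disperse across the whole
#' cell. The dispersion state is summarised by a single fraction `d`: 0 for
#' fully aggregated, 1 for fully dispersed. Two mixing rules are provided:
#'
#' * `"areal"` (default): pigment coverage scales the area of the light
#'   path that is filtered, so
#'   `T_eff = 100 * (1 - d) + d * T_dispersed`.
#' * `"optical_density"`: pigment dispersion scales absorbance
#'   (Beer-Lambert in `d`), so `T_eff = 100 * (T_dispersed / 100)^d`.
#'
#' Areal mixing is the default because granule dispersion mainly changes
#' the covered area rather than the optical path length through pigment.
#'
#' @param d Dispersion fraction in \[0, 1\].
#' @param dispersed_T Transmittance [spectrum()] of the fully dispersed
#'   state.
#' @param mode `"areal"` or `"optical_density"`.
#' @return Transmittance [spectrum()] at dispersion `d`.
#' @export
effective_transmittance <- function(d, dispersed_T,
                                    mode = c("areal", "optical_density")) {
  mode <- match.arg(mode)
  stopifnot(is_spectrum(dispersed_T),
            dispersed_T$kind == "transmittance_percent",
            length(d) == 1, is.finite(d))
  if (d < 0 || d > 1) {
    stop("dispersion fraction d = ", d, " outside [0, 1]")
  }
  v <- switch(mode,
              areal = 100 * (1 - d) + d * dispersed_T$value,
              optical_density = 100 * (dispersed_T$value / 100)^d)
  spectrum(dispersed_T$wavelength_nm, v, "transmittance_percent")
}

#' SWS1 feedback signal across dispersion states
#'
#' Models the optical feedback a chromatophore imposes on the SWS1
#' photoreceptor beneath it: the relative quantal catch
#' `1 - attenuation(T_eff(d))` as the pigment moves from fully aggregated
#' (`d = 0`, catch 1 by construction) to fully dispersed (`d = 1`, catch
#' equal to one minus the dispersed-state attenuation). Because dispersed
#' pigment absorbs the short wavelengths the opsin is sensitive to, the
#' curve decreases with `d` — dispersion suppresses, aggregation restores,
#' the photoreceptor signal.
#'
#' @param dispersed_T Dispersed-state transmittance [spectrum()].
#' @param d_grid Dispersion fractions in \[0, 1\].
#' @param template Sensitivity template (default 415-nm A1 template over
#'   400-500 nm on the dispersed spectrum's grid).
#' @param illuminant Optional illuminant [spectrum()] (flat equal-quantum
#'   by default).
#' @param type Optional chromatophore type label carried into the output.
#' @param mode Mixing rule, see [effective_transmittance()].
#' @return Data frame with columns `d`, `relative_catch`, and `type`.
#' @export
feedback_curve <- function(dispersed_T, d_grid = seq(0, 1, by = 0.05),
                           template = NULL, illuminant = NULL,
                           type = NA_character_,
                           mode = c("areal", "optical_density")) {
  mode <- match.arg(mode)
  stopifnot(all(d_grid >= 0 & d_grid <= 1))
  if (is.null(template)) {
    tgrid <- dispersed_T$wavelength_nm[dispersed_T$wavelength_nm <= 520]
    template <- a1_template(415, tgrid)
  }
  catch <- vapply(d_grid, function(d) {
    te <- effective_transmittance(d, dispersed_T, mode = mode)
    1 - sws1_attenuation(te, template, illuminant = illuminant)
  }, 0.0)
  data.frame(d = d_grid, relative_catch = catch, type = type,
             stringsAsFactors = FALSE)
}
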