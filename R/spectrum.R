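#' Wavelength-sampled spectra
#'
#' A `spectrum` is the package's basic container for any quantity sampled on
#' a wavelength grid: raw spectrometer counts, percent transmittance,
#' absorbance, or a dimensionless sensitivity. It is a plain list with three
#' fields so that downstream code can rely on a single, validated shape.
#'
#' @param wavelength_nm Numeric vector of wavelengths in nanometres,
#'   strictly increasing.
#' @param value Numeric vector of the sampled quantity, same length as
#'   `wavelength_nm`.
#' @param kind One of `"counts"`, `"transmittance_percent"`, `"absorbance"`,
#'   `"sensitivity"`. Kind-specific range checks are applied:
#'   transmittance must lie in \[0, 100\] and sensitivity in \[0, 1\]
#'   (up to a small numerical tolerance).
#'
#' @return An object of class `spectrum`.
#' @export
#' @examples
#' s <- spectrum(400:700, rep(50, 301), "transmittance_percent")
#' resample(s, c(450.5, 500.25))
spectrum <- function(wavelength_nm, value,
                     kind = c("counts", "transmittance_percent",
                              "absorbance", "sensitivity")) {
  kind <- match.arg(kind)
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) != length(value)) {
    stop("wavelength and value vectors differ in length (",
         length(wavelength_nm), " vs ", length(value), ")")
  }
  if (length(wavelength_nm) < 1L || anyNA(wavelength_nm) ||
      any(!is.finite(wavelength_nm))) {
    stop("wavelengths must be finite and non-empty")
  }
  if (any(diff(wavelength_nm) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  tol <- 1e-9
  if (kind == "transmittance_percent" &&
      (min(value) < -tol || max(value) > 100 + tol)) {
    stop("transmittance_percent values must lie in [0, 100]; range is [",
         signif(min(value), 6), ", ", signif(max(value), 6),
         "] (apply clip_transmittance() first if this is measurement noise)")
  }
  if (kind == "sensitivity" && (min(value) < -tol || max(value) > 1 + tol)) {
    stop("sensitivity values must lie in [0, 1]")
  }
  structure(list(wavelength_nm = wavelength_nm, value = value, kind = kind),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d samples, %.6g-%.6g nm>\n",
              x$kind, length(x$wavelength_nm),
              min(x$wavelength_nm), max(x$wavelength_nm)))
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "spectrum")

#' Build a uniform wavelength grid with exact endpoints
#'
#' `seq(from, to, by = step)` accumulates floating-point error for steps such
#' as 0.3 nm; this helper derives the sample count from the span and uses
#' `length.out` so the endpoints are hit exactly. The number of samples is
#' `round((to - from) / step) + 1`, so 400-700 nm at 0.3 nm gives 1001.
#'
#' @param from,to Grid endpoints in nm (`from < to`).
#' @param step Grid step in nm.
#' @return Numeric vector of wavelengths.
#' @export
spectral_grid <- function(from, to, step) {
  stopifnot(is.numeric(from), is.numeric(to), is.numeric(step),
            length(from) == 1, length(to) == 1, length(step) == 1,
            from < to, step > 0)
  n <- round((to - from) / step)
  seq(from, to, length.out = n + 1L)
}

#' Default wavelength grids
#'
#' The modelling grid spans 350-700 nm at 0.5 nm so that templates peaking
#' near 415 nm are represented below the instrument range, while
#' microspectrophotometry outputs are reported on the instrument's own
#' 400-700 nm window at ~0.3 nm resolution.
#'
#' @return Numeric wavelength vector.
#' @export
default_model_grid <- function() spectral_grid(350, 700, 0.5)

#' @rdname default_model_grid
#' @export
default_msp_grid <- function() spectral_grid(400, 700, 0.3)

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; the target grid must lie within the span of the
#' source grid (no extrapolation). The spectrum kind is preserved.
#'
#' @param spec A [spectrum()].
#' @param grid Target wavelength vector (strictly increasing).
#' @return A [spectrum()] on `grid`.
#' @export
resample <- function(spec, grid) {
  stopifnot(is_spectrum(spec))
  grid <- as.numeric(grid)
  lo <- min(spec$wavelength_nm)
  hi <- max(spec$wavelength_nm)
  if (min(grid) < lo || max(grid) > hi) {
    stop(sprintf(
      "resampling would extrapolate: requested [%.6g, %.6g] nm outside source span [%.6g, %.6g] nm",
      min(grid), max(grid), lo, hi))
  }
  v <- stats::approx(spec$wavelength_nm, spec$value, xout = grid,
                     method = "linear", ties = "ordered")$y
  spectrum(grid, v, spec$kind)
}

#' Clip transmittance values to the physical range
#'
#' Measurement noise can push sample counts above the reference, producing
#' transmittance slightly above 100% (or below 0%). Values are clipped to
#' \[0, 100\] and the number of clipped samples is reported via a message so
#' that heavy clipping is visible in pipeline logs.
#'
#' @param value Numeric vector of percent transmittance.
#' @param quiet Suppress the clipping message.
#' @return Clipped numeric vector.
#' @export
clip_transmittance <- function(value, quiet = FALSE) {
  n_clip <- sum(value < 0 | value > 100)
  if (n_clip > 0 && !quiet) {
    message(n_clip, " transmittance sample(s) clipped to [0, 100]")
  }
  pmin(pmax(value, 0), 100)
}

#' Trapezoid integral of a spectrum-valued integrand
#'
#' @param wavelength_nm Wavelength vector.
#' @param value Integrand values.
#' @return Scalar integral.
#' @keywords internal
spec_integral <- function(wavelength_nm, value) {
  pracma::trapz(wavelength_nm, value)
}

#' Read and write spectra as two-column delimited text
#'
#' The on-disk format is two columns, `wavelength_nm<sep>value`, with
#' optional `#`-prefixed header lines. The writer emits tab-separated values
#' with a `# kind=<kind>` header; the reader accepts tab- or comma-separated
#' data and recovers the kind from the header (falling back to the `kind`
#' argument when the file carries none).
#'
#' @param spec A [spectrum()].
#' @param path File path.
#' @param kind Fallback kind for headerless files.
#' @return `read_spectrum` returns a [spectrum()]; `write_spectrum` returns
#'   `path` invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(is_spectrum(spec))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# kind=", spec$kind), con)
  utils::write.table(
    data.frame(w = spec$wavelength_nm, v = spec$value),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path, kind = "counts") {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  km <- regmatches(hdr, regexpr("kind=\\S+", hdr))
  if (length(km) > 0) kind <- sub("^kind=", "", km[[1]])
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0) stop("no data rows in ", path)
  sep <- if (grepl(",", body[[1]], fixed = TRUE)) "," else "\t"
  df <- utils::read.table(text = body, sep = sep, header = FALSE,
                          col.names = c("wavelength_nm", "value"))
  spectrum(df$wavelength_nm, df$value, kind)
}
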