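#' Pigment transmittance models for the three chromatophore types
#'
#' Dispersed-pigment transmittance is modelled per type:
#'
#' * melanophore — melanin absorbs broadly, so transmittance is low and
#'   rises slowly and uniformly with wavelength:
#'   `T(lambda) = T400 + k * (lambda - 400)`.
#' * erythrophore / xanthophore — carotenoid-type pigments show a sharp
#'   transition from a low short-wavelength floor to high long-wavelength
#'   transmittance, modelled as a floored logistic:
#'   `T(lambda) = T_lo + (T_hi - T_lo) / (1 + exp(-(lambda - m)/s))`,
#'   with the erythrophore midpoint `m` above the xanthophore one (red
#'   pigment cuts on at longer wavelengths than yellow).
#'
#' The default parameters were calibrated once, by one-dimensional root
#' finding against the package's own transition and attenuation estimators,
#' so that the noiseless pipeline reproduces transition wavelengths of
#' about 550 nm (erythrophore) and 488 nm (xanthophore) and 415-nm-template
#' attenuations of about 0.90 / 0.85 / 0.50
#' (melanophore / erythrophore / xanthophore). They ship frozen here.
#'
#' @param type Chromatophore type.
#' @param ... Model parameters overriding the calibrated defaults:
#'   `T400`, `k` for melanophores; `T_lo`, `T_hi`, `m`, `s` for the
#'   logistic types.
#' @return A `pigment_model` list.
#' @export
pigment_model <- function(type = c("melanophore", "erythrophore",
                                   "xanthophore"), ...) {
  type <- match.arg(type)
  defaults <- switch(type,
    melanophore = list(T400 = 9.07, k = 0.03),
    erythrophore = list(T_lo = 15, T_hi = 90, m = 578.19, s = 10),
    xanthophore = list(T_lo = 50, T_hi = 95, m = 546.58, s = 9))
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown parameter(s) for ", type, ": ",
         paste(unknown, collapse = ", "))
  }
  pars <- utils::modifyList(defaults, override)
  structure(c(list(type = type), pars), class = "pigment_model")
}

#' @rdname pigment_model
#' @export
default_pigment_models <- function() {
  list(melanophore = pigment_model("melanophore"),
       erythrophore = pigment_model("erythrophore"),
       xanthophore = pigment_model("xanthophore"))
}

#' Evaluate a pigment model's dispersed transmittance
#'
#' @param model A [pigment_model()].
#' @param grid Wavelength grid in nm.
#' @return A [spectrum()] of kind `"transmittance_percent"`.
#' @export
pigment_transmittance <- function(model, grid = default_msp_grid()) {
  stopifnot(inherits(model, "pigment_model"))
  v <- if (model$type == "melanophore") {
    model$T400 + model$k * (grid - 400)
  } else {
    model$T_lo + (model$T_hi - model$T_lo) /
      (1 + exp(-(grid - model$m) / model$s))
  }
  spectrum(grid, pmin(pmax(v, 0), 100), "transmittance_percent")
}

#' Configuration for the synthetic scan generator
#'
#' Default replication mirrors the study design this generator emulates:
#' 3 fish, 20 cells per type and fish (60 cells per type), scans on a
#' 400-700 nm grid at 0.3 nm. Noise is multiplicative Gaussian on counts
#' (spectrometer counts at bright-lamp levels are gain-scaled, not
#' shot-limited) with coefficient of variation `cv`; a Poisson mode is
#' available. Per-cell biological variation is a lognormal optical-density
#' multiplier with log-sd `jitter_sd`.
#'
#' @param n_fish Number of fish.
#' @param cells_per_fish Cells per chromatophore type per fish.
#' @param types Chromatophore types to generate.
#' @param grid Wavelength grid.
#' @param reference_peak Peak reference counts of the lamp spectrum.
#' @param cv Coefficient of variation of the count noise (0 disables).
#' @param jitter_sd Log-sd of the per-cell optical-density multiplier
#'   (0 disables).
#' @param noise `"gaussian"` or `"poisson"`.
#' @param seed Master seed; per-cell streams are derived from it so any
#'   subset of cells is reproducible in isolation.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_fish = 3, cells_per_fish = 20,
                             types = c("melanophore", "erythrophore",
                                       "xanthophore"),
                             grid = default_msp_grid(),
                             reference_peak = 30000,
                             cv = 0.03, jitter_sd = 0.1,
                             noise = c("gaussian", "poisson"),
                             seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(n_fish >= 1, cells_per_fish >= 1, cv >= 0, jitter_sd >= 0,
            reference_peak > 0, length(grid) >= 2)
  types <- match.arg(types, several.ok = TRUE)
  structure(list(n_fish = as.integer(n_fish),
                 cells_per_fish = as.integer(cells_per_fish),
                 types = types, grid = as.numeric(grid),
                 reference_peak = reference_peak,
                 cv = cv, jitter_sd = jitter_sd, noise = noise,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Deterministic per-cell seed stream: a Lehmer step of the master seed
# offset by the cell index, kept inside the 32-bit integer range.
derive_seed <- function(master, idx) {
  as.integer(((as.numeric(master) %% 2147483647) * 48271 + idx) %% 2147483647)
}

# Smooth tungsten-halogen-like lamp spectrum (Planck radiator at 3200 K),
# scaled so its maximum on the grid equals `peak` counts.
lamp_counts <- function(grid, peak) {
  lam <- grid * 1e-9
  c2 <- 1.438777e-2
  b <- lam^-5 / (exp(c2 / (lam * 3200)) - 1)
  peak * b / max(b)
}

#' Generate synthetic microspectrophotometry scans
#'
#' Emulates paired through-cell and unpigmented-reference scans: the
#' reference is a smooth lamp-shaped count spectrum, and the sample is the
#' reference multiplied by the pigment model's transmittance, raised to a
#' per-cell lognormal optical-density exponent, with multiplicative count
#' noise on both scans. With `cv = 0` and `jitter_sd = 0` the recovered
#' transmittance equals the pigment model curve exactly.
#'
#' @param config A [generator_config()].
#' @param models Named list of [pigment_model()] objects, one per type in
#'   `config$types` (default [default_pigment_models()]).
#' @return List of [msp_scan()] objects
#'   (`n_fish * cells_per_fish * length(types)` of them).
#' @export
generate_scans <- function(config = generator_config(),
                           models = default_pigment_models()) {
  stopifnot(inherits(config, "generator_config"))
  missing_models <- setdiff(config$types, names(models))
  if (length(missing_models) > 0) {
    stop("no pigment model for type(s): ",
         paste(missing_models, collapse = ", "))
  }
  grid <- config$grid
  ref_mu <- lamp_counts(grid, config$reference_peak)
  scans <- list()
  idx <- 0L
  for (ty in config$types) {
    t_model <- pigment_transmittance(models[[ty]], grid)$value
    for (fish in seq_len(config$n_fish)) {
      for (cell in seq_len(config$cells_per_fish)) {
        idx <- idx + 1L
        cell_seed <- derive_seed(config$seed, idx)
        scans[[idx]] <- local({
          set.seed(cell_seed)
          g <- exp(stats::rnorm(1, 0, config$jitter_sd))
          t_cell <- 100 * (t_model / 100)^g
          smp_mu <- ref_mu * t_cell / 100
          noisy <- function(mu) {
            if (config$noise == "gaussian") {
              mu * (1 + stats::rnorm(length(mu), 0, config$cv))
            } else {
              stats::rpois(length(mu), mu)
            }
          }
          msp_scan(
            sample = spectrum(grid, noisy(smp_mu), "counts"),
            reference = spectrum(grid, noisy(ref_mu), "counts"),
            cell_id = sprintf("%s_f%d_c%02d", substr(ty, 1, 4), fish, cell),
            fish_id = sprintf("fish%d", fish),
            chromatophore_type = ty)
        })
      }
    }
  }
  scans
}

#' Write and read a scan directory
#'
#' The on-disk layout is the one the pipeline reads: one
#' `<cell>_sample.tsv` and `<cell>_reference.tsv` pair per cell (the
#' two-column spectrum text format) plus a tab-separated `manifest.tsv`
#' with columns `cell_id`, `fish_id`, `chromatophore_type`,
#' `sample_path`, `reference_path`.
#'
#' @param scans List of [msp_scan()] objects.
#' @param dir Directory (created if needed).
#' @return `write_scans` returns the manifest path invisibly; `read_scans`
#'   returns a list of [msp_scan()] objects.
#' @export
write_scans <- function(scans, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(scans, function(sc) {
    sp <- paste0(sc$cell_id, "_sample.tsv")
    rp <- paste0(sc$cell_id, "_reference.tsv")
    write_spectrum(sc$sample, file.path(dir, sp))
    write_spectrum(sc$reference, file.path(dir, rp))
    data.frame(cell_id = sc$cell_id, fish_id = sc$fish_id,
               chromatophore_type = sc$chromatophore_type,
               sample_path = sp, reference_path = rp,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(mpath)
}

#' @rdname write_scans
#' @export
read_scans <- function(dir) {
  mpath <- if (dir.exists(dir)) file.path(dir, "manifest.tsv") else dir
  if (!file.exists(mpath)) stop("no manifest found at ", mpath)
  manifest <- utils::read.table(mpath, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  if (nrow(manifest) == 0) stop("manifest at ", mpath, " lists no scans")
  base <- dirname(mpath)
  lapply(seq_len(nrow(manifest)), function(i) {
    msp_scan(
      sample = read_spectrum(file.path(base, manifest$sample_path[i])),
      reference = read_spectrum(file.path(base, manifest$reference_path[i])),
      cell_id = manifest$cell_id[i],
      fish_id = manifest$fish_id[i],
      chromatophore_type = manifest$chromatophore_type[i])
  })
}

# SWS1-typical residues imposed on the bovine backbone at the default
# tuning sites (violet-sensitive configuration); the fixture pair is built
# from this sequence.
sws1_site_residues <- function() {
  c(`46` = "F", `49` = "F", `52` = "T", `86` = "F", `90` = "S", `93` = "T",
    `97` = "S", `109` = "A", `113` = "E", `114` = "A", `116` = "M",
    `118` = "T", `265` = "W")
}

#' Generate a fixture pair of SWS1-like sequences
#'
#' Builds two synthetic, same-length SWS1-like amino-acid sequences that
#' differ from each other exactly at the requested bovine-numbered
#' positions. The first sequence is a bovine-rhodopsin backbone carrying
#' SWS1-typical residues at the 13 default tuning sites (plus a few
#' conservative decorations elsewhere, so the pair is not literally the
#' reference); the second applies the substitution spec on top. These are
#' deliberately synthetic stand-ins that emulate the tuning-site content of
#' a real retinal/dermal SWS1 pair, not any organism's full sequence.
#'
#' @param subs Character vector of substitution notations applied to the
#'   second sequence (default `c("S97C", "M116V")`). The stated reference
#'   residue must match the first sequence at that position.
#' @param ids Names for the two sequences.
#' @return A `Biostrings::AAStringSet` of length 2.
#' @export
generate_fixture_sequences <- function(subs = c("S97C", "M116V"),
                                       ids = c("anchor_sws1_synthetic",
                                               "query_sws1_synthetic")) {
  backbone <- strsplit(as.character(bovine_rhodopsin()[[1]]), "")[[1]]
  site_res <- sws1_site_residues()
  backbone[as.integer(names(site_res))] <- site_res
  # conservative decorations at non-tuning positions
  decorations <- c(`33` = "A", `150` = "S", `230` = "I", `320` = "S")
  backbone[as.integer(names(decorations))] <- decorations

  spec <- parse_substitutions(subs)
  alt <- backbone
  if (nrow(spec) > 0) {
    if (any(spec$site < 1 | spec$site > length(backbone))) {
      stop("substitution position(s) outside the reference length (",
           length(backbone), ")")
    }
    for (i in seq_len(nrow(spec))) {
      have <- backbone[spec$site[i]]
      if (have != spec$ref[i]) {
        stop("reference residue mismatch at position ", spec$site[i],
             ": sequence has ", have, ", substitution says ", spec$ref[i])
      }
      alt[spec$site[i]] <- spec$alt[i]
    }
  }
  out <- Biostrings::AAStringSet(c(paste(backbone, collapse = ""),
                                   paste(alt, collapse = "")))
  names(out) <- ids
  out
}
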