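# dermopsin

Analysis pipeline for **dermal photoreception in colour-changing fish**:
how the pigment state of skin chromatophores (melanophores, erythrophores,
xanthophores) optically gates the light reaching SWS1-opsin
photoreceptors that sit directly beneath them, and what that implies for
sensory feedback on colour change.

The package implements four connected pieces of quantitative method:

* **Tuning-site λ_max estimation** — map opsin amino-acid sequences onto
  bovine rhodopsin (RH1) numbering by global alignment, call
  substitutions at the 13 SWS1 spectral tuning sites, and estimate the
  peak sensitivity by anchor-plus-shift:
  `interval = λ_anchor + Σ [shift intervals]`, keeping the anchor as the
  point estimate whenever a zero net shift is consistent with the summed
  interval.
* **Vitamin-A1 pigment template** — the α-band modified log-normal
  `S(x) = exp(−a₀x²(1 + a₁x + a₂x²))`, `x = log10(λ/λ_max)`
  (`a₀ = 380`, `a₁ = 6.09`, `a₂ = 3a₁²/8`), peak-normalised and
  shape-invariant in log-wavelength.
* **Microspectrophotometry (MSP) processing** — per-cell transmittance
  `T(λ) = 100·I_cell/I_ref`, per-type means ± s.e.m., transition
  wavelengths via the tangent at the steepest smoothed slope
  (`λ₀ − T(λ₀)/T′(λ₀)`, exactly `m − 2s` for a logistic rise), and
  opsin-weighted attenuation
  `A = 1 − ∫T·S·E dλ / ∫100·S·E dλ` over 400–500 nm.
* **Optical feedback model** — relative SWS1 quantal catch as a function
  of pigment dispersion `d ∈ [0, 1]`, with effective transmittance
  `T_eff = 100(1−d) + d·T_dispersed` (areal mixing; a Beer–Lambert mode
  is switchable).

A seeded synthetic-data generator reproduces the emulated study design
(3 fish × 20 cells × 3 types, 400–700 nm at 0.3 nm, multiplicative count
noise, lognormal per-cell pigment density) plus fixture SWS1-like
sequence pairs, so everything runs and is tested without external data.

## Worked example

```r
library(dermopsin)

# lambda_max of a dermal SWS1 given its two tuning-site substitutions
fx <- generate_fixture_sequences()              # synthetic SWS1-like pair
subs <- compare_tuning_sites(map_to_bovine(fx[1]), map_to_bovine(fx[2]))
subs$notation
#> [1] "S97C"  "M116V"
estimate_lambda_max(415, subs)
#> lambda_max estimate: 415 nm (interval [411, 415] nm, anchor 415 nm, 2 substitution(s))

# chromatophore optics from simulated scans (noise disabled here)
sm <- summarize_types(generate_scans(generator_config(cv = 0, jitter_sd = 0)))
summary_table(sm)
#>           type n_cells transition_nm attenuation_fraction
#> 1  melanophore      60            NA            0.9000167
#> 2 erythrophore      60      549.9954            0.8499962
#> 3  xanthophore      60      487.9941            0.4999747
```

Reading the output: the two sequences differ at tuning sites 97 and 116;
those substitutions shift SWS1 λ_max by at most a few nm downward, so the
estimate stays centred on the 415-nm anchor with a negative-leaning
interval. The erythrophore and xanthophore mean spectra switch from
opaque to transparent with tangent intercepts near 550 nm and 488 nm;
melanophores rise too gradually to show a transition (`NA`). Weighted by
the 415-nm A1 template, dispersed pigment removes ~90% / 85% / 50%
(melanophore / erythrophore / xanthophore) of the light available to the
underlying SWS1 receptors — the feedback signal modelled by
`feedback_curve()`.

## Analysis workflow

Numbered drivers under `analysis/` chain the full reproduction and write
tables under `results/` (run from the repository root, in order):

```sh
Rscript analysis/01_simulate.R          # scans + fixture sequences
Rscript analysis/02_msp_summaries.R     # means, transitions, attenuations
Rscript analysis/03_tuning_sites.R      # substitution calling
Rscript analysis/04_lambda_max.R        # anchor-plus-shift estimate
Rscript analysis/05_feedback.R          # catch vs dispersion curves
Rscript analysis/06_reproduce_report.R  # one headline-number table
```

Each driver logs its fully resolved configuration (defaults < YAML file
via `DERMOPSIN_CONFIG` < flags) under `results/logs/`.

## Documentation

The methods vignette
(`vignettes/dermal-photoreception-methods.Rmd`) describes the models,
their assumptions, the estimator design (including why the transition
smoothing window is wide), the generator calibration, and known
limitations.
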