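---
title: "Methods: chromatophore optics and dermal SWS1 spectral modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatophore optics and dermal SWS1 spectral modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermopsin)
```

## The system being modelled

Colour-changing fish rearrange pigment granules inside dermal
chromatophores — black melanophores, red erythrophores, and yellow
xanthophores — between an aggregated state (a small central mass, skin
appears light) and a dispersed state (pigment spread across the cell, skin
appears dark or coloured). In hogfish skin, cells expressing a
short-wavelength-sensitive (SWS1) opsin sit directly beneath the
chromatophores, so every photon reaching them has first passed through the
overlying pigment. Dispersed pigment of all three types absorbs most
strongly exactly where a violet-peaking SWS1 pigment is sensitive, which
suggests an optical feedback channel: the dispersion state of the
chromatophore modulates the light reaching its own underlying
photoreceptor.

This package makes that chain quantitative and testable end to end:

1. estimate the dermal SWS1 peak sensitivity (λ~max~) from amino-acid
   substitutions at known spectral tuning sites (`tuning` module);
2. expand λ~max~ into a full sensitivity curve with a vitamin-A1 pigment
   template (`a1_template()`);
3. reduce single-cell microspectrophotometry (MSP) scans to per-type mean
   transmittance spectra, transition wavelengths, and template-weighted
   attenuations (`transmittance()`, `summarize_types()`);
4. turn the dispersed-state optics into a feedback signal — relative SWS1
   quantal catch as a function of pigment dispersion (`feedback_curve()`).

A seeded generator (`generate_scans()`, `generate_fixture_sequences()`)
produces every input, so the full analysis runs and is tested without any
external data.

## λ~max~ from tuning sites

Ciliary opsins are strongly conserved, so the peak sensitivity of an
unmeasured SWS1 pigment can be estimated by anchoring on a close homolog
with a known λ~max~ and accounting for substitutions at the residue
positions known (from site-directed mutagenesis) to tune SWS1 spectra.
Positions are reported in bovine rod opsin (RH1) numbering, obtained here
by global pairwise alignment (Needleman–Wunsch, BLOSUM62, gap open 10 /
extend 1) against the packaged 348-residue bovine reference. With this
level of conservation the numbering is insensitive to the scoring details.

The packaged tuning-site list (13 positions: 46, 49, 52, 86, 90, 93, 97,
109, 113, 114, 116, 118, 265) is assembled from the SWS1 mutagenesis
literature; reviews differ slightly at the margins, so the list ships as
editable data rather than a constant, and analyses can substitute their
own. Each known substitution maps to an interval of λ~max~ shift in nm
(`sws1_shift_table()`, also editable); pairs without published
measurements get a conservative zero-centred ±3 nm interval, since known
SWS1 tuning-site switches move λ~max~ by at most a few nanometres.

The estimate is anchor-plus-shift: the interval is the anchor plus the sum
of the shift intervals, and the point estimate *keeps the anchor* whenever
a zero net shift is consistent with the summed interval. This encodes the
field's "centering on" convention: small negative-leaning shift evidence
widens the interval downward without moving the centre. Only when the
summed interval excludes zero does the point move to the interval
midpoint.

```{r lmax}
est <- estimate_lambda_max(415, c("S97C", "M116V"))
est
```

The worked default: a 415-nm anchor with substitutions S97C and M116V
(shift intervals [−1, 0] and [−3, 0] nm) gives a point estimate of 415 nm
with interval [411, 415] nm, inside the vertebrate SWS1 range
(360–440 nm).

## The A1 pigment template

`a1_template()` uses the modified log-normal α-band form: with
$x = \log_{10}(\lambda/\lambda_{max})$,

$$S(x) = \exp\!\left(-a_0 x^2 (1 + a_1 x + a_2 x^2)\right),
\qquad a_0 = 380,\; a_1 = 6.09,\; a_2 = \tfrac{3}{8} a_1^2 .$$

The curve depends on wavelength only through the ratio
$\lambda/\lambda_{max}$, so it is shape-invariant on a log-wavelength axis
and exactly 1 at the peak. The fit is only trustworthy near the α band;
outside $\lambda/\lambda_{max} \in [0.58, 1.30]$ the template evaluates to
0 with a warning. The β band (secondary UV peak) is omitted by default: for
a 415-nm pigment observed through a 400–700 nm instrument window it
contributes almost nothing, and the downstream attenuation summaries use
the single α-band curve. The test suite cross-checks the template against
an independently coded Govardovskii-type A1 closed form (base constants);
the two published forms agree to within 0.013 over 380–480 nm at a 415-nm
peak. (The λ~max~-refined variant of that family narrows at violet peaks
and differs from any log-wavelength-invariant form by up to ~0.05 on the
long limb — a known discrepancy between published templates, not an
implementation artefact.)

## MSP processing

Transmittance divides the through-cell counts by a reference scan taken
through adjacent unpigmented tissue, cancelling the lamp spectrum and all
shared optics: $T(\lambda) = 100\,I_{cell}/I_{ref}$, clipped to [0, 100]
(noise can push the ratio slightly above 1; clipping events are
reported). Per-type summaries average the per-cell transmittance spectra
pointwise on the 400–700 nm instrument grid at 0.3 nm (1001 samples) and
carry the standard error of the mean.

**Transition wavelength.** Erythrophore and xanthophore spectra switch
sharply from a low short-wavelength floor to high long-wavelength
transmittance. The reported transition is where the tangent at the
steepest point of the rise meets zero transmittance:
$\lambda_0 - T(\lambda_0)/T'(\lambda_0)$, with $\lambda_0$ the wavelength
of maximum smoothed slope. For a logistic rise with midpoint $m$ and scale
$s$ this equals $m - 2s$ exactly, which the tests exploit as a closed-form
oracle. Melanophores rise too gradually to show a transition; a curve
whose maximum slope stays below 0.2 %/nm (configurable) is reported as
having none.

Smoothing is a Savitzky–Golay filter. The default window is 29 nm with a
cubic derivative kernel — much wider than the sampling step, for a
reason: at 0.3 nm resolution, finite-difference slopes are
noise-dominated, and locating the *argmax* of a noisy derivative
systematically selects upward noise excursions, biasing the slope up and
the intercept toward $\lambda_0$ (we measured about +4 nm bias for the
default xanthophore under the generator's default noise with a 5 nm
window). Widening the window suppresses that selection bias; the cubic
derivative kernel (the smoothing kernel itself is the local quadratic one,
since even and odd orders pair in Savitzky–Golay filters) cancels the
third-order slope bias that would otherwise distort sharp logistic rises.
At 29 nm the logistic oracle is still reproduced to ~0.33 nm (noiseless),
and across 50 default-noise replicate sets the estimates scatter within
about 4 nm with mean bias below 0.2 nm. Window and order are configuration
keys.

**Attenuation.** The opsin-weighted attenuation is one minus the quantal
catch behind the pigment relative to the unfiltered catch,

$$A = 1 - \frac{\int T(\lambda)\, S(\lambda)\, E(\lambda)\, d\lambda}
              {\int 100\, S(\lambda)\, E(\lambda)\, d\lambda},$$

integrated by the trapezoid rule over 400–500 nm (the instrument range
intersected with the short-wavelength band where the 415-nm template
carries weight). The illuminant $E$ defaults to flat equal-quantum; a
tabulated illuminant can be supplied in the two-column spectrum text
format. A zero-weight window is an error rather than a silent 0/0.

## The feedback model

The dispersion state is a single fraction $d$ (0 aggregated, 1 fully
dispersed). Effective transmittance interpolates between a clear aperture
and the dispersed-state spectrum by areal coverage,
$T_{eff} = 100(1-d) + d\,T_{disp}$, because granule dispersion mainly
changes the *covered area* of the light path rather than the optical path
length through pigment. A Beer–Lambert alternative
($T_{eff} = 100 (T_{disp}/100)^d$) is implemented and switchable for
sensitivity analyses. The feedback signal is the relative quantal catch
$1 - A(T_{eff}(d))$: equal to 1 at $d = 0$ by construction, and
non-increasing in $d$ for any non-negative illuminant. No temporal
dynamics are modelled — the activation and signalling properties of the
dermal receptors are unknown, so the model is a static input–output map,
and a single chromatophore layer is assumed (stacked-layer filtering would
multiply transmittances).

```{r feedback}
g <- default_msp_grid()
disp <- pigment_transmittance(pigment_model("melanophore"), g)
fb <- feedback_curve(disp, d_grid = c(0, 0.5, 1), type = "melanophore")
fb
```

## What the synthetic generator emulates — and what it does not

The generator reproduces the study design it stands in for: 3 fish × 20
cells per chromatophore type per fish (60 cells per type), paired
sample/reference scans on the 400–700 nm grid at 0.3 nm. The reference is
a smooth tungsten-halogen-like (3200 K Planck) count spectrum; the sample
is the reference multiplied by the type's dispersed-pigment transmittance.
Noise is multiplicative Gaussian on counts (default cv 0.03) — bright-lamp
spectrometer counts are gain-scaled rather than shot-limited — with a
Poisson mode available. Biological cell-to-cell variation is a lognormal
optical-density exponent per cell (log-sd 0.1). Per-cell random streams
are derived deterministically from one master seed, so any subset of cells
is reproducible in isolation. The true per-cell variance of the original
measurements is unreported (only the s.e.m. is plotted), so these noise
defaults are plausible rather than estimated, and are stated here as such.

Dispersed-pigment transmittance models: melanophores are a slow uniform
linear rise, $T = T_{400} + k(\lambda - 400)$; erythrophores and
xanthophores are floored logistics,
$T = T_{lo} + (T_{hi} - T_{lo})/(1 + e^{-(\lambda - m)/s})$. The floor
$T_{lo}$ is essential: a logistic through zero cannot simultaneously put
the erythrophore transition near 550 nm and leave ~15% transmittance over
the 400–500 nm band, yet both are features of the measured spectra the
generator emulates. Defaults were calibrated once by one-dimensional root
finding against the package's own estimators so that the noiseless
pipeline lands on transitions of ~550 nm (erythrophore) and ~488 nm
(xanthophore) and 415-nm-template attenuations of ~0.90 / 0.85 / 0.50
(melanophore / erythrophore / xanthophore); the fitted values are frozen
as the `pigment_model()` defaults.

Passing tests on these synthetics demonstrate that the estimators are
correct, unbiased under the stated noise model, and internally consistent
— they cannot demonstrate robustness to features real scans may have that
the generator lacks: baseline drift, dark-current error, focus variation
across cells, pigment-class heterogeneity, or reference regions that are
not perfectly unpigmented.

## Numerical and design choices

* **Grids.** Modelling grid 350–700 nm at 0.5 nm (templates peaking at
  415 nm extend below the instrument range); MSP reporting grid 400–700 nm
  at 0.3 nm (1001 samples), built with exact endpoints via
  `spectral_grid()`. Resampling is linear and refuses to extrapolate.
* **Tie-breaks and degenerate inputs.** The transition search excludes the
  filter's edge transients; ties in the derivative argmax resolve to the
  shortest wavelength. Empty scan sets, non-overlapping grids,
  non-positive reference counts, and zero-weight attenuation windows are
  errors with informative messages, not silent numbers.
* **Problem sizes.** The default test and analysis runs use the full
  60-cells-per-type design; replicate-set properties use 50 seeds. These
  sizes were chosen to match the emulated study design while keeping a
  complete run in the order of seconds.
* **Known limitations.** The λ~max~ estimate inherits the anchor's
  uncertainty, which is not propagated (the anchor's own λ~max~ is treated
  as exact); the tuning-site list and shift table are reconstructions from
  the literature and deliberately editable; the feedback model is purely
  optical and single-layer, with no receptor activation function.
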