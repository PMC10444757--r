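# Independent oracles used to cross-check the package's own computations.

# Second published closed form for vitamin-A1 pigment absorbance
# (Govardovskii-type alpha band, base constants), coded independently of
# a1_template() and peak-normalised on the evaluation grid.
govardovskii_a1 <- function(lambda_max_nm, grid) {
  x <- lambda_max_nm / grid
  v <- 1 / (exp(69.7 * (0.88 - x)) + exp(28 * (0.922 - x)) +
              exp(-14.9 * (1.104 - x)) + 0.674)
  v / max(v)
}

# Analytic logistic transmittance curve; its tangent at the steepest point
# meets zero transmittance at exactly m - 2 s.
logistic_T <- function(grid, m, s, T_hi = 100) {
  spectrum(grid, T_hi / (1 + exp(-(grid - m) / s)), "transmittance_percent")
}

flat_T <- function(grid, level) {
  spectrum(grid, rep(level, length(grid)), "transmittance_percent")
}
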