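Package: dermopsin
Title: Dermal Photoreception Analysis: Opsin Tuning, Chromatophore
    Optics, and Sensory Feedback Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dermal photoreception in colour-changing
    fish. Estimates the peak spectral sensitivity (lambda_max) of SWS1
    opsins from amino-acid substitutions at known spectral tuning sites in
    bovine rhodopsin numbering, evaluates vitamin-A1 visual pigment
    absorbance templates, processes single-cell microspectrophotometry
    scans of chromatophores into transmittance spectra, transition
    wavelengths and opsin-weighted attenuation summaries, and models the
    optical feedback signal that chromatophore pigment dispersion imposes
    on underlying short-wavelength photoreceptors. A seeded synthetic-data
    generator produces microspectrophotometry scans and fixture opsin
    sequences so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
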