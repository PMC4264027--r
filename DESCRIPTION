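Package: poresignal
Title: Signal Analysis for Low-Noise Solid-State Nanopore Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for ionic-current blockade sensing with
    solid-state nanopores: power-spectral-density noise decomposition into
    flicker, white, dielectric and capacitive terms with fitting and
    spectrum-shaped noise synthesis; a conductance-versus-geometry pore
    model with effective membrane thickness estimation; synthetic
    generation of patch-clamp-like current traces with rectangular
    translocation blockades and Bessel low-pass filtering; threshold-based
    event detection with baseline correction; and Gaussian single-peak and
    two-component mixture fitting of residual currents for ssDNA
    homopolymer discrimination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
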