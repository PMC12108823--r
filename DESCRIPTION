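Package: dielspec
Title: Cole-Cole Modelling and Fitting of Tissue Dielectric Spectra
Version: 0.1.0
Authors@R: person("dielspec", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Forward evaluation of first-order Cole-Cole and linearly
    frequency-augmented ("improved") Cole-Cole dielectric relaxation models
    for biological tissue, a bounded simulated-annealing fitter minimising a
    relative average fitting error with per-component R-squared reporting,
    a synthetic spectrum generator emulating in vivo lung measurements
    across ventilator tidal volumes, Kruskal-Wallis group comparison of
    dielectric quantities at ISM frequencies, and CSV/JSON input-output with
    a command-line interface tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
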