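Package: tengneuron
Title: Triboelectric Nanogenerator Stimulation of a Hodgkin-Huxley Axon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled model of a vertical contact-separation triboelectric
    nanogenerator (TENG) driving an unmyelinated axon. Computes the device's
    open-circuit voltage and capacitance as functions of electrode gap for
    flat and micropatterned surfaces (closed-form parallel-plate model and a
    2D finite-volume Poisson solver with dielectric interfaces and floating
    electrodes), couples the tabulated device curve into an extended
    Hodgkin-Huxley cable equation through the motional displacement-current
    terms, and extracts spike-train metrics (firing rate, full width at half
    maximum, inter-pulse delay, resting-potential shift) from the simulated
    membrane traces. Includes reproducible contact-release speed and surface
    morphology sweeps and synthetic-trace generators for validating the
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
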