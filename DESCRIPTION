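Package: opendwell
Title: Dwell-Time Kinetics of RNA Polymerase Open-Complex Dynamics from
    Magnetic-Tweezers Extension Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to extract open-complex formation and dissociation rate
    constants of bacterial RNA polymerase from single-molecule magnetic
    tweezers extension traces. Provides phase-type (first-passage) dwell-time
    densities for promoter kinetic schemes and the exact conversion between
    exponential-mixture fit parameters and microscopic rate constants; a
    Gillespie-based synthetic trace generator with ground-truth dwell records;
    bottom-up L1 change-point segmentation of two-level extension signals with
    Allan-deviation trace diagnostics; maximum-likelihood fitting of one- and
    two-exponential dwell-time distributions with BIC model selection and
    bootstrap errors; binding (hyperbolic), Arrhenius and coupled
    binding-Arrhenius temperature fits plus salt-sensitivity slopes;
    supercoiling geometry (transcription-bubble size, bent-DNA length, twist
    shifts from rotation-extension curves); and deterministic population
    simulations of promoter species.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Matrix,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
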