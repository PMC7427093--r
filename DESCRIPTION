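Package: ddstate
Title: Oligomeric State and Kinetics of Membrane Receptor Death Domains from NMR Observables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines the oligomeric state of small proteins from NMR
    rotational and translational diffusion measurements via Stokes-Einstein
    and Stokes-Einstein-Debye hydrodynamics and a calibrated radius-to-mass
    power law. Includes TRACT-style estimation of rotational correlation
    times from TROSY/anti-TROSY relaxation decay pairs, Stejskal-Tanner
    fitting of pulsed-field-gradient echo attenuation with extrapolation to
    infinite dilution, first-order deamidation and closed-form second-order
    membrane-confined dimerization kinetics, a lipid-to-protein-ratio
    estimator for cell membranes, chemical-shift perturbation and secondary
    chemical-shift analytics, two-state population quantification by
    lineshape deconvolution, and seeded synthetic-data generators that
    emulate every input the analyses consume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    Biostrings,
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
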