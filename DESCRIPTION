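Package: aquaflux
Title: Osmotic Shrinkage Kinetics and Activation Thermodynamics of Water
    Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of stopped-flow light-scattering measurements of
    osmotic vesicle shrinkage and extraction of the activation
    thermodynamics of facilitated water permeation. Implements the
    Lambert-W closed-form solution of the osmotic shrinkage equation;
    exponential, per-trace analytical and global activation-energy fits
    of normalized scattering traces from mixed populations of empty
    liposomes and proteoliposomes; Monte-Carlo studies of how
    permeability scatter, temperature range, temperature bias and
    reconstitution heterogeneity propagate into activation-energy error;
    transition-state-theory extraction of the enthalpic and entropic
    barriers with a transmission-coefficient correction; and
    transmission-coefficient estimation from single-file permeation
    trajectories. Includes a seeded synthetic stopped-flow data
    generator with Poisson channel-count statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    pracma,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
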