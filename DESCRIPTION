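Package: trpa1pore
Title: Outer-Pore Biophysics of TRPA1: Synthetic Patch Clamp, Divalent Block,
    Surface Potential and Pore Sizing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analyses of ion permeation and block through the
    outer pore of the TRPA1 channel, driven by a synthetic patch-clamp data
    generator so that every stage is testable without laboratory recordings.
    Simulates episodic single-channel and whole-cell sweeps (two open
    conductance levels, voltage ramps, leak, Bessel-filtered Gaussian noise,
    concentration-dependent divalent block); idealizes sweeps into events and
    amplitude histograms; builds averaged open-channel current-voltage
    relations and branch slope conductances; fits a Woodhull-type
    voltage-dependent dissociation constant inside a Hill block model across
    blocker concentrations; converts blocker-affinity and conductance ratios
    into surface-potential changes and evaluates screened-Coulomb vestibule
    potentials; and sizes organic cations by the vertex-distance method to
    estimate the minimum open-pore diameter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mclust,
    minpack.lm,
    signal
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
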