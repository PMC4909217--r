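Package: ifsim
Title: Monte Carlo Simulation of Intermediate Filament Assembly by End-to-End
    Annealing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained, continuum-space Monte Carlo simulator of
    intermediate filament (IF) assembly. Unit-length filaments (ULFs) are
    modelled as bead-bond chains that diffuse by geometric trial moves in a
    fully periodic box and elongate exclusively by end-to-end annealing.
    Includes worm-like-chain persistence-length calibration from simulated
    radius-of-gyration curves, filament length-distribution analytics
    (ULF conversion, number- and mass-weighted histograms, persistence-length
    normalized binning, elongation constants, concentration conversions),
    deterministic synthetic-data generators for testing, and a command-line
    interface for running simulations and analyses.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(load = "source")
NeedsCompilation: yes
RoxygenNote: 7.3.3
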