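Package: hybridff
Title: Hybrid United-Atom/Coarse-Grained Force-Field Parameterization and
    Aggregation Analysis Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and testing hybrid-resolution (united-atom plus
    coarse-grained) nonbonded force fields for peptide condensate simulation.
    Implements the cross-resolution energy model (Lennard-Jones with pair-specific
    cross terms, reaction-field electrostatics, and a three-way energy
    decomposition), desk-scale Langevin and Metropolis samplers with umbrella
    biasing, weighted-histogram (WHAM) reconstruction of potentials of mean force
    with first-minimum descriptors, two-stage parameter calibration (pair-specific
    Lennard-Jones fitting against reference free-energy profiles, then scalar
    rescaling of coarse-grained and cross-resolution well depths against
    radius-of-gyration distributions), and an aggregation-analysis suite covering
    cluster kinetics power laws, inter-cluster encounter statistics, beta-strand
    detection, and amyloid registry classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
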