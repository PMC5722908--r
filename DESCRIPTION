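Package: stepmd
Title: Enhanced and Adaptive Sampling Molecular Dynamics on Toy Domain-Docking Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for studying enhanced-sampling and
    adaptive-seeding molecular dynamics protocols on small synthetic bead
    systems that emulate a nuclease domain docking onto its cleavage site.
    Provides a Langevin (BAOAB) dynamics engine with pluggable bias
    potentials, the accelerated-MD dual-boost potential with parameter
    estimation and exponential reweighting, targeted-MD steering on the
    best-fit RMSD with a linear schedule and weak positional restraints,
    and a step-by-step adaptive ensemble protocol that reseeds replica
    ensembles from the snapshot minimising a geometric-mean distance
    metric. Trajectory analysis covers fit-excluded principal component
    analysis, labelled site-pair distance series, per-group RMSD with
    global or self fitting, RMSD-based clustering with medoid
    representatives, metal-coordination geometry checks, and cross-group
    interaction-energy decomposition, together with campaign manifest
    bookkeeping and simulation-cell ion arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    bio3d,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
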