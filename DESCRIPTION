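Package: proxidyn
Title: Network-Proximity Drug Screening and Post-Simulation Trajectory Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for network-based drug repositioning
    and downstream structural validation. Screens drugs against a disease gene
    set on a protein-protein interaction network using a degree-weighted
    closest-distance measure with size-matched random reference distributions
    and z-scores; analyses molecular-dynamics trajectories (Kabsch
    superposition, RMSD, RMSF, residue cross-correlation matrices, coordinate
    PCA, free-energy landscapes); aggregates MM-PBSA energy components into
    binding free energies with strength classification; applies Lipinski
    rule-of-five and effect-size-based differential-expression filters; and
    ships seed-deterministic synthetic-data generators (scale-free networks
    with planted drug-disease proximity structure, correlated Gaussian
    fluctuation trajectories, two-group expression matrices) so every stage is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
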