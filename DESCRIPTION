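Package: pocketome
Title: Pocket Maps, Contact-Network State Analysis and Site Censuses for
    GPCR Structure Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the ensemble of binding pockets (the
    "pocketome") across G-protein-coupled receptor structures. Converts
    docked molecular-probe poses into pharmacophore-feature density grids
    using a dampened 27-voxel recording kernel, combines per-structure grids
    into master grids and exports them for molecular visualisation;
    computes residue contact maps under a van der Waals plus buffer
    criterion, builds class-specific binary contact fingerprints and
    analyses activation states by principal components, reporting
    normalised state-specific contact importances per site; scores
    receptorome-wide sequence identity, similarity and polarity of
    site-defining residues; and tabulates the occupancy of known allosteric
    sites by crystallisation additives and co-purified molecules. Seeded
    synthetic-data generators (idealised seven-helix bundles, probe-pose
    clouds, fingerprint cohorts, site sequences, hetero-component
    placements) make the full pipeline testable without any structure
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
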