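Package: hingescan
Title: Contact-Change Hotspot Analysis of Hinge-Protein Trajectories for
    Biosensor Insertion-Site Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate effector-insertion sites in hinge-type
    binding proteins (periplasmic binding proteins such as the maltose
    binding protein) from replicate molecular dynamics trajectories.
    Classifies simulations as open or closed from RMSD, computes
    per-residue pseudo-dihedral and RMSF difference profiles, builds
    Pearson correlation matrices of hysteresis-defined inter-residue
    contact distances against time, clusters contiguous matrix hotspots
    and filters them by percentile, assembles circularly-permuted-GFP
    insertion construct sequences with the standard duplicated-residue
    linkers, and scores plate-reader fluorescence assays by dF/F0 with a
    viability call. Includes a synthetic two-lobe hinge generator and a
    simulated plate-assay generator so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
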