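Package: covbench
Title: Benchmarking and Selection of Covalent Docking Tools
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for evaluating covalent docking programs against curated
    co-crystal benchmarks. Curates covalent complexes with auditable filters
    (resolution, ligand size, cysteine/serine anchor, cofactor proximity),
    classifies electrophilic warheads into a reaction-class taxonomy with
    substructure patterns and MDL RXN templates, computes symmetry-aware no-fit
    heavy-atom RMSDs between docked poses and the crystallographic ligand, and
    aggregates per-complex results into the precision (median-of-medians),
    generality (mark-counting) and robustness selection criteria, with
    success/failure profiling, anchor-site descriptors (solvent accessible
    surface area and side-chain dihedral), and a synthetic benchmark generator
    with analytically known pose accuracy for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stats,
    utils,
    igraph,
    ChemmineR,
    bio3d,
    yaml,
    jsonlite,
    ggplot2,
    readr,
    generics,
    methods,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ChemmineOB,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
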