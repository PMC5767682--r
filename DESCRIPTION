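Package: condock
Title: Consensus Small-Molecule Docking Analysis for Pentameric
    Ligand-Gated Ion Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for consensus docking studies of allosteric
    modulators in transmembrane receptor sites. Implements
    element-constrained Hungarian-assignment ligand RMSD, cross-engine
    pose agreement filtering, search-region refinement, flexible-residue
    selection, Borda rank aggregation over heterogeneous docking scores,
    hierarchical RMSD clustering of binding modes across a chemical
    series, ligand-residue interaction reports, segment-based density-fit
    scores (cross-correlation and Manders' overlap), register-shift
    alignment correction, and a deterministic synthetic fixture
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    optparse
Config/testthat/edition: 3
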