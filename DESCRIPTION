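Package: bsfenet
Title: Binding Selectivity Free-Energy Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Thermodynamic identity algebra and maximum-likelihood network
    analysis for alchemical binding free-energy data. Combines absolute
    (ABFE), relative (RBFE), receptor-hopping (RHFE) and receptor-swapping
    (RSFE) free-energy measurements into consistent per-complex binding
    free energies and per-ligand binding selectivity free energies (BSFEs)
    using a generalized DiffNet weighted least-squares solver with anchored
    reference nodes. Includes first-order uncertainty propagation on the
    2-sigma reporting convention, consistency diagnostics (direct versus
    indirect comparisons, RMSD, two-sided significance tests, cycle
    closure, forward/reverse hysteresis), a synthetic-network generator
    for parameter-recovery studies, edge-list file input/output, packaged
    host-guest and serine-protease benchmark tables, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
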