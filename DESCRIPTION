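Package: pfasscreen
Title: QSAR Modeling and Virtual Screening of PFAS Binding to Nuclear
    Hormone Receptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes 2D topological descriptors (halogen percentage,
    radial centric information index, path/walk-2 Randic shape index,
    total path count) from SMILES structures of per- and polyfluoroalkyl
    substances (PFAS), calibrates and validates multiple linear
    regression QSAR models of receptor docking scores (internal
    leave-one-out and external Q2 statistics, concordance correlation,
    Y-scrambling), assesses the leverage-based applicability domain
    (Williams plot, Insubria graph), and screens compound libraries into
    binding-probability classes for five nuclear hormone receptors
    (PPAR alpha/beta/gamma, TR alpha/beta) using frozen published model
    equations and thresholds. Includes a synthetic PFAS generator
    (homologous series and structural decoys) so the whole pipeline is
    reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    igraph,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
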