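Package: aconiqstr
Title: Molecular-Field QSTR Modelling and Network Target Screening for
    Aconitine Alkaloids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An in-silico toxicology pipeline for aconitine-type alkaloid
    cardiotoxicity. Computes CoMFA-style steric/electrostatic and
    CoMSIA-style Gaussian similarity fields on a rectangular lattice around
    pre-aligned 3D structures (with Gasteiger PEOE partial charges and
    energy-column filtration), fits partial least squares models of pLD50
    on the field descriptors with leave-one-out q2, SEE, F, predictive r2
    and per-field fraction contributions, assesses the applicability domain
    by leverage and standardized residuals (Williams plot data), screens
    protein-protein interaction networks with subgraph, betweenness and
    closeness centrality plus top-decile overlap and candidate-cluster
    quality filtering, and scores the consistency of docking fit-score
    rankings against experimental toxicity rankings with normalized
    discounted cumulative gain. Seeded synthetic-data generators make every
    stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ChemmineOB,
    ChemmineR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
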