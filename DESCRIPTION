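Package: capscaffold
Title: Combinatorial Assembly and Expression-Noise Analysis of the Yeast Cap-Binding Complex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how the abundance of the translation-initiation
    scaffold eIF4G controls protein synthesis rate and gene-expression noise in
    budding yeast. The package enumerates the random-order assembly network of
    the cap-binding complex (eIF4G and mRNA as scaffolds; eIF4A, eIF4E, Ded1 and
    Pab1 as bivalent ligands), builds the corresponding mass-action kinetic
    model, solves its quasi-steady state, scans translation flux against factor
    abundance to expose the prozone (bell-shaped) response, and fits rate
    parameters to abundance-rate data by alternating Hooke-Jeeves pattern search
    with particle-swarm optimisation. A companion single-cell pipeline computes
    expression-noise statistics: radial density gating of flow-cytometry events,
    coefficient-of-variation curves versus gate radius, the dual-reporter
    intrinsic-noise estimator, smFISH count summaries and growth-competition
    population fractions. A synthetic-data module generates cytometry events,
    mRNA counts, competition colony counts and noisy abundance-rate datasets so
    every stage is testable without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    stats,
    utils,
    xml2,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
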