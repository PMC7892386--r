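Package: oagenes
Title: Gene Perturbation Effects in Osteoarthritis Animal Models and
    Network-Based Target Prioritisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing curated gene-perturbation experiments in
    animal models of osteoarthritis (OA). Infers per-experiment gene effects
    on OA joint-damage severity from the direction of modulation and the
    observed phenotype, combines them into per-gene consensus labels with
    explicit handling of conflicting and no-effect observations, and
    quantifies cross-study, cross-approach and cross-model consistency.
    Integrates the curated genes with differential-expression result tables
    via Fisher exact overlap tests and chi-square effect-class proportion
    tests with Benjamini-Hochberg correction. Prioritises new candidate
    genes by network diffusion with restart over a protein-protein
    interaction network, validated by repeated k-fold recovery of held-out
    known genes, and applies a differential-expression and interaction-count
    candidate filter. Includes synthetic-data generators (curation tables,
    DE tables, scale-free networks with a planted module) so the whole
    pipeline is testable without external downloads, and a single-config
    pipeline runner with a machine-readable report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
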