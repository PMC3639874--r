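Package: oascreen
Title: Optimal-Assignment Molecular Similarity with Evolutionary Edge-Weight
    Optimization for Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ligand-based virtual screening with the edge-weighted
    optimal-assignment (OA) molecular similarity. Molecules are compared by an
    optimal (Hungarian) mapping of their atoms under recursive, decay-weighted
    atom-environment similarities; per-atom assignment-edge weights of a query
    molecule are optimized against virtual-screening metrics (AUC, BEDROC,
    ROC enrichment, arithmetically weighted ROC enrichment) with constriction
    particle swarm optimization or differential evolution variants. Includes
    the weight-redistribution transform for per-atom visualization, a
    split/multirun evaluation harness, and a synthetic planted-pharmacophore
    dataset generator for self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineR,
    ChemmineOB,
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
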