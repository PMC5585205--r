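Package: powerggm
Title: Co-Expression Networks, Power-Graph Compression and Genetic
    Association for Inflammatory Transcriptional Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrative network-analysis toolkit for factorial
    (condition x time) expression studies of the microglial response to
    systemic inflammation. Identifies per-time-point up/down response
    clusters (standardized mean differences with Welch tests and
    Benjamini-Hochberg control), reconstructs co-expression networks as
    shrinkage graphical Gaussian models with empirical-null local false
    discovery rate edge selection, profiles network topology (small-world
    sigma, clustering, power-law degree exponent), performs lossless
    power-graph compression of protein-protein interaction networks with
    detection of super-power nodes (SPNs), assesses subnetwork
    connectivity by degree-matched permutation, computes hypergeometric
    gene-set / transcription-factor-target enrichment and multi-set
    overlap tests, and tests genotype-phenotype and cis-eQTL association
    with self-contained SNP-set permutation. A synthetic-data module
    generates every input with planted, recorded ground truth so each
    stage has a recovery-based test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    MASS,
    seqinr,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
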