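Package: phenoscore
Title: Disease-Causality Scoring of Gene Perturbations from Phenotype
    Ontology Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the probability that perturbing a gene causes the
    phenotypes of a complex disease, using ontology-structured phenotype
    annotations of mouse mutants. Per-phenotype C4.5-style decision-tree
    ensembles with resampled negative gene sets yield phenotype
    probabilities, which are combined into a per-gene disease score via
    -log10 frequency weights and normalized to [0,1]. Includes
    cross-validated ROC evaluation, specificity cutoffs, fold enrichment,
    Monte-Carlo interaction-count tests on gene networks, SNP-proximity
    analyses for GWAS loci, and a seeded synthetic-data generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
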