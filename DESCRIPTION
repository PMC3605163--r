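Package: GOwise
Title: Knowledge-Driven Feature Selection over Gene Ontology Term Subsets
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Embeds prior biological knowledge into two-class gene signature
    discovery. A gene expression matrix is partitioned into Gene Ontology
    (GO) term indexed subsets using platform annotations; each subset is
    analyzed with embedded l1l2 (elastic-net-type) regularized feature
    selection under nested K-fold cross-validation, or with plain
    regularized least squares when the subset is small. GO terms whose
    cross-validated classification error falls below a threshold are called
    significant, and probesets selected in enough outer folds are reported
    as properly selected. Significant terms are clustered by normalized
    Resnik semantic similarity over the GO graph and drawn on the minimal
    ancestor subgraph; recovery of benchmark gene and term lists is scored
    as coverage. A synthetic fixture generator produces complete offline
    input bundles with controlled signal.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    data.table,
    igraph,
    jsonlite,
    yaml,
    parallel,
    S4Vectors,
    SummarizedExperiment
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
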