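Package: dpcnet
Title: Differential Partial Correlation Networks for Multi-Omics Disease
    Module Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies disease-related gene modules by integrating gene
    expression, DNA methylation and somatic mutation data over a
    protein-protein interaction scaffold. Builds per-group Pearson
    correlation networks, prunes indirect edges with first-order partial
    correlation tests, takes the symmetric difference between tumor and
    normal networks, scores differential co-methylation of the surviving
    edges, and ranks hub genes by somatic variation frequency. Includes
    validation statistics (hypergeometric enrichment, cross-validated SVM
    classification with ROC/AUC, single-linkage cityblock clustering), a
    seeded synthetic multi-omics generator with known ground truth, and a
    resumable file-based pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    pROC,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
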