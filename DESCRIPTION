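Package: cellTWAS
Title: Cell-Type-Aware Transcriptome-Wide Association Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for cell-type-aware transcriptome-wide association
    studies (TWAS) from bulk tissue data. Estimates the proportion of a
    cell type of interest in bulk samples by joint modelling of signature
    gene expression and a prior enrichment score; trains cell-type-level
    genetically regulated expression (GReX) prediction models by mixture
    decomposition with symmetric elastic-net penalization and bootstrap
    stability selection; tests disease association under a composite null
    with the Cauchy combination of cell-type-level p-values; and ships a
    simulation engine for type-I-error and power studies against a
    tissue-level elastic-net baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    jsonlite,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
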