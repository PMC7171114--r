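Package: rotadti
Title: Drug-Target Interaction Prediction with PSSM-DCT Descriptors and
    Rotation Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-target interactions (DTIs) from sequence-derived
    protein descriptors and substructure drug fingerprints.  Protein targets
    are encoded by applying a two-dimensional discrete cosine transform to
    their PSI-BLAST position-specific scoring matrices and keeping the 400
    low-frequency coefficients; drugs are encoded as PubChem 881-bit
    substructure fingerprints.  Candidate pairs drawn from a bipartite
    interaction network (with balanced negative down-sampling) are classified
    by a Rotation Forest ensemble built from per-subset PCA rotations and
    unpruned decision trees.  Includes a pseudo amino acid composition
    baseline encoder, stratified cross-validation and grid-search utilities,
    a synthetic data generator with a planted interaction signal, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rpart,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    glmnet,
    optparse
Config/testthat/edition: 3
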