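Package: epiGA
Title: Genetic-Algorithm Ensemble Prediction of Immunogenic T-Cell Epitopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the immunogenicity of HLA-A2 restricted 9-mer T-cell
    epitopes from sequence alone. Eighteen sequence-derived feature encoders
    (physicochemical propensity profiles, composition and dipeptide profiles,
    sparse one-hot profiles, Smith-Waterman similarity profiles, contact
    potentials, CTD descriptors, Moran/Geary/Moreau-Broto autocorrelations,
    quasi-sequence-order, pseudo and amphiphilic pseudo amino-acid
    composition, and predicted-structure descriptors) feed per-feature
    random-forest base classifiers combined by score averaging; a genetic
    algorithm searches the feature-subset space maximizing internal
    cross-validation AUC. Includes repeated stratified cross-validation,
    standard binary classification metrics, significance testing, and a
    synthetic peptide generator with controllable planted signal for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    tools,
    Biostrings,
    randomForest,
    seqinr,
    stats,
    utils
Suggests:
    pROC,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
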