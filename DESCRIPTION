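Package: spvec
Title: Skip-Gram Embeddings of Drugs and Proteins for Drug-Target
    Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns dense vector representations of small-molecule drugs
    and protein targets with a from-scratch Skip-gram model trained by
    negative sampling: SMILES strings are tokenized into atom-aware
    "sentences" and protein sequences into non-overlapping amino-acid
    3-mer "words". Token vectors are summed into molecule (SMILES2Vec)
    and protein (ProtVec) features and concatenated into pair features
    (SPVec) for drug-target interaction (DTI) classification. Includes
    classical baselines (166-key MACCS fingerprints, 20-dimensional
    amino-acid composition), dataset construction following affinity,
    inorganic and sequence-identity filters with temporal old/new
    splits and seeded negative sampling, a repeated stratified
    cross-validation bench (GBDT, random forest, neural network) with
    AUC/accuracy/precision/recall/F1 reporting, cosine nearest-neighbor
    analysis and t-SNE projections of the embedding space, and a fully
    seeded synthetic-data generator with planted class structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ChemmineR,
    ChemmineOB,
    xgboost,
    ranger,
    nnet,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
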