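Package: grlmn
Title: Drug-Disease Association Prediction over a Molecular Association
    Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts drug-disease associations by fusing node attributes
    (MeSH-DAG disease semantic similarity, grouped 3-mer sequence
    composition, autoencoder-compressed circular fingerprints) with LINE
    graph embeddings learned over a heterogeneous molecular association
    network of drugs, diseases, proteins, miRNAs and lncRNAs, and
    classifying candidate pairs with a random forest under stratified
    five-fold cross-validation.  Includes a block-model simulator that
    generates complete synthetic inputs with planted drug-disease signal
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    e1071,
    graphics,
    ranger,
    Rcpp,
    rpart,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
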