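Package: prokdomain
Title: Genomic-Feature Encoding and Machine-Learning Classification of
    Archaea and Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes annotated prokaryotic genomes as a 77-feature vector of
    per-component nucleotide statistics (whole genome, CDS, rRNA, tRNA, ncRNA)
    and four information-theoretic scores per component (Shannon entropy,
    finite-sequence topological entropy, and two Chargaff second-parity
    scores), applies genome inclusion filters, and trains and evaluates four
    classifiers (regularized logistic regression, random forest, RBF support
    vector machine, single-hidden-layer neural network) for discriminating
    Archaea from Bacteria. Includes stratified splitting, random-forest-based
    recursive feature elimination, repeated stratified cross-validation with
    in-fold minority upsampling and centring/scaling, imbalance-aware metrics
    (MCC, per-class error rates, ROC AUC), exploratory summaries, a GenBank
    flat-file reader/writer, and a synthetic annotated-genome generator with
    controlled class-specific composition and strand-parity structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    randomForest,
    e1071,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
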