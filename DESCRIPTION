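Package: mdapredict
Title: Microbe-Drug Association Prediction with a Convolutional Encoder and
    Bernoulli Random Forest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts unobserved microbe-drug associations from a bipartite
    table of known associations plus drug and microbe similarity matrices.
    Every microbe-drug pair is represented by the concatenation of the
    microbe's integrated-similarity row and the drug's integrated-similarity
    row; a small one-dimensional convolutional network compresses these
    vectors to half their length, and a Bernoulli Random Forest -- a random
    forest variant that splits each tree's data into a structural part
    (shapes the tree) and an estimation part (fills the leaves), with
    Bernoulli trials governing candidate-feature count and split-point
    choice -- scores the encoded pairs. Includes integrated-similarity
    construction (side-effect Jaccard, structure-similarity cutoff),
    balanced negative sampling (uniform and density-aware stratified),
    repeated five-fold cross-validation with rank-against-unlabeled AUC,
    precision-recall curves, per-drug top-k ranking with new-drug masking,
    and a seeded synthetic-data generator with planted block structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
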