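Package: HerbTopics
Title: Prescription Function Prediction with Pair-Aware Supervised Topic
    Models and Multilabel Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the therapeutic function labels of Traditional
    Chinese Medicine prescriptions (formulae) by two complementary routes.
    The first mines herb-pair compatibility rules from prescription
    co-occurrence (a combined support/dependency score) and feeds them into
    a pair-aware supervised topic model -- a Labeled-LDA extension in which
    a mined herb pair shares a single function assignment during collapsed
    Gibbs sampling -- with posterior-threshold multilabel prediction. The
    second builds dosage-standardized TFIDF features and herbal attribute
    vectors (nature and flavor, channel tropism, efficiency) and trains
    one-vs-rest multilabel classifiers. Shared micro-averaged evaluation,
    k-fold cross-validation and a synthetic corpus generator with known
    ground truth are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    e1071,
    rpart,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
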