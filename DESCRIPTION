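Package: phenotext
Title: Phrase-Based Phenotyping of Clinical Narratives with Convolutional
    Text Classifiers and Saliency Interpretation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring binary patient phenotypes (for example
    alcohol abuse or obesity) from free-text clinical notes. Implements a
    multi-width convolutional text classifier with max-over-time pooling
    trained per phenotype, gradient-based word and phrase saliency for
    model interpretation, dictionary-based clinical concept extraction with
    NegEx-style negation and negation-separated TF-IDF bag-of-concepts
    features, n-gram/bag-of-words and pooled-embedding baselines,
    skip-gram-with-negative-sampling word embedding pre-training, a
    reproducible synthetic discharge-summary corpus generator with gold
    phrase spans, and a patient-grouped evaluation harness (precision,
    recall, F1, rank-based AUC, Cohen's kappa, chi-squared model
    comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    methods,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
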