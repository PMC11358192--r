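Package: knowjudge
Title: Judging Knowledgeability from the Specificity and Veracity of Language
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how evaluators judge other people's
    knowledgeability from short image descriptions.  Implements mode
    aggregation of multi-rater statement counts with intraclass-correlation
    reliability, knowledgeability scoring from multiple-choice accuracy, a
    split-half resampling ceiling for pairwise discrimination, slice-sampling
    Bayesian logistic regression for informant discriminability and evaluator
    choice (including a knowledgeability-by-veracity interaction),
    Savage-Dickey Bayes factors with robustness curves, default-prior Bayes
    factors for correlations and t tests, a calibrated synthetic-study
    generator, and an end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
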