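Package: traitlearn
Title: Hybrid Rescorla-Wagner Models of Social Trait Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits and validates hybrid Rescorla-Wagner learning models of how
    people learn the personality traits of others from trial-by-trial
    feedback. Five model families combine two social knowledge structures:
    reference points (average trait ratings of a comparison group, blended
    into estimates by a weighting parameter) and granularity (coarse learning
    of one value per Big-Five factor versus fine-grained generalization of
    prediction errors across traits in proportion to their correlations).
    Includes variants with stereotype or self-rating reference points and
    separate learning rates for positive and negative prediction errors.
    Provides synthetic experiment generation, least-squares model fitting
    with BIC scoring, fixed-effects and random-effects (exceedance
    probability) model comparison, parameter recovery, model confusion
    matrices, task-optimality analysis, and model-free behavioural
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
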