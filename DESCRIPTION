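Package: cohacc
Title: Coherence and Accuracy of Probability Judgments via Bayesian Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the link between the coherence and the
    accuracy of human probability judgments in a poker-flop / urn paradigm.
    Enumerates three-card flops exactly (including suit-isomorphism classes),
    builds the nine-question stimulus set with exact true probabilities,
    simulates judgments with a Bayesian sampler response model, scores
    additivity incoherence (Dutch-book sure loss), inaccuracy, extension
    errors and matching-question inconsistency, and runs the inferential
    pipeline: unconfounded cross-subtask Pearson correlations, percentile
    bootstrap of the mean correlation, partial correlations removing
    covariates, Welch tests, and a Monte-Carlo power analysis reconciling
    prior null results for a four-question medical-risk design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
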