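Package: sathmm
Title: Covariate-Dependent Hidden Markov Models for Self-Adapted Test
    Choice Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models item-difficulty choice sequences from self-adapted tests
    with Gaussian-emission hidden Markov models whose initial-state and
    transition probabilities are multinomial-logistic functions of observed
    covariates (goal condition, pre-test score, accumulated correctness and
    confidence). Provides EM estimation with a scaled forward-backward pass,
    Viterbi decoding, an AIC/BIC/likelihood-ratio model-comparison ladder,
    expected-probability effect surfaces, sequence descriptives, and a
    calibrated synthetic-cohort generator for a 583-participant, 40-item
    self-adapted general-knowledge test with seven difficulty levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nnet,
    withr
Config/testthat/edition: 3
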