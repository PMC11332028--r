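Package: rpemem
Title: Reward Prediction Errors, Perceptual Memorability, and Recognition Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Generative simulation and Bayesian analysis of a two-arm reversal
    bandit with trial-unique memorable stimuli followed by an old/new
    recognition test. Implements likelihoods and Bayesian fitting for three
    decision models (Rescorla-Wagner, win-stay/lose-shift, Bayesian hidden-state
    filter) with WAIC comparison, parameter recovery and identifiability;
    extraction of trial-level reward prediction errors; a Wiener
    first-passage-time likelihood and hierarchical drift-diffusion regressions
    of recognition reaction times on reward prediction error or stimulus
    memorability; Bayesian mixed-effects logistic regression of memory success;
    exploratory factor analysis of symptom surveys with promax rotation and
    ten Berge scores; and subject-level moderation and TOST equivalence
    analyses. A synthetic-data module makes every stage runnable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    rjags,
    coda,
    MASS,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
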