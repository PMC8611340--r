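Package: affectdyn
Title: Dynamic Models of Momentary Affective Experience
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative models of trial-by-trial momentary affect (valence and
    arousal) under sequential stimulus presentation: an exponential-decay
    integration model and a weighted-impact (Rescorla-Wagner-style) updating
    model, with per-participant maximum-likelihood fitting, AIC-based
    group-level random-effects Bayesian model selection (protected exceedance
    probabilities), model- and parameter-recovery simulation harnesses,
    posterior-predictive validation, and a lagged relevance-interaction
    regression analysis. Includes a synthetic-experiment generator emulating a
    goal-relevance attention paradigm: a normed image catalog, balanced block
    schedules with relevance cues and targets, and model-based rating
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
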