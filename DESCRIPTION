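Package: clickflash
Title: Stochastic Audiovisual Sequence Generation and Multisensory
    Causal-Inference Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying temporal causal inference with stochastic
    click-flash sequences. Generates event trains with a frame-triplet
    algorithm (one event per 50-ms bin, minimum 33-ms inter-event gap) or a
    fixed inter-event-interval (60/120 ms) algorithm; extracts temporal
    correspondence cues (proportion of synchronous click-flash pairs, maximum
    click-flash offset, windowed normalized cross-correlation); fits
    cumulative-Gaussian psychometric functions by Metropolis MCMC with flat
    priors; derives best-cue and optimal cue-integration threshold
    predictions with posterior propagation; performs random-effects Bayesian
    model selection with exceedance probabilities; computes
    response-conditioned cross-correlogram difference functions with
    permutation nulls; and fits a logistic mixed-effects model of causality
    judgements with parametric-bootstrap inference. A synthetic-observer
    module simulates complete rate-discrimination and causality-judgement
    datasets so the whole pipeline runs without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
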