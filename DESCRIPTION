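Package: metashift
Title: Two-Step Confidence Re-Assessment: Simulation and Metacognitive
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the two-step confidence paradigm in visual
    metacognition, in which observers give two consecutive confidence
    ratings on each perceptual decision and the second rating may not
    repeat the first. Provides a generative signal-detection observer
    with a two-up-one-down adaptive staircase and tunable, partially
    independent metacognitive noise on the two reports; participant
    exclusion rules and up/down/extreme shift labelling; classical
    equal-variance signal-detection primitives (d-prime, criterion,
    edge-corrected rates); maximum-likelihood meta-d' estimation for
    first, second and trial-averaged confidence; a second-step
    metacognitive sensitivity statistic with a permutation-based
    empirical chance level; and group-level paired tests, effect sizes
    and exact noncentral-t power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
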