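Package: searchvpl
Title: Ideal-Observer Modelling of Perceptual Learning in Orientation Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a Bayesian ideal observer for present/absent visual
    search in which the reliability of orientation representations depends on
    the orientation (near-cardinal vs oblique) and improves with training
    according to an exponential learning curve. Provides four nested model
    variants (Reliability, Learning, Reliability-and-Learning, and
    Reliability-Learning-Group), simulation-based least-squares fitting with
    multi-start Nelder-Mead and common random numbers, AICc model comparison,
    leave-one-observer-out cross-validated r-squared with a noise ceiling,
    training-only fits that predict transfer to the swapped orientation, and
    a synthetic-cohort generator emulating a two-group, multi-session
    perceptual-learning study.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
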