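Package: ssdmodels
Title: Bayesian and Discriminative Observer Models for Trans-Saccadic
    Displacement Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for the Saccadic Suppression of
    Displacement (SSD) paradigm, in which observers judge whether (or by how
    much) a target moved during a saccade. Implements a categorical Bayesian
    ideal observer whose decision curve is the survivor function of a
    noncentral chi-square distribution, a continuous reliability-weighted
    Bayesian observer, a two-layer delta-rule (Perceptron) learner with
    prior-dependent input contexts, and a convex combination of the Bayesian
    and discriminative outputs. Includes a synthetic trial-schedule generator
    emulating cue-signaled prior blocks with graded image noise, psychometric
    analysis (four-parameter logistic fits, intercepts, signal detection
    theory measures, bootstrap confidence intervals), maximum-likelihood and
    least-squares model fitting with parameter-recovery harnesses, and
    scenario drivers that reproduce the models' qualitative predictions as
    summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
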