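Package: stepsense
Title: Bayesian-Observer Analysis of Sensorimotor Uncertainty in Stepping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses a virtual-reality stepping paradigm in
    which an unseen backward shift is added to a body-controlled cursor and
    participants compensate by combining noisy visual feedback with a learned
    prior over the shift. Provides the Bayesian ideal-observer generative
    model, a synthetic crossover-cohort generator (three groups, two visits,
    with or without transcutaneous electric nerve stimulation), the
    deviation-on-shift regression whose slope measures prior influence and
    whose root-mean-squared error measures sensorimotor uncertainty, virtual
    time-to-contact computation from centre-of-pressure sway traces, and the
    group-by-visit mixed-effects analysis with Tukey pairwise comparisons and
    the visit-1 and difference-in-differences stimulation contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
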