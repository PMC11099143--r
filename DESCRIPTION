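Package: patsim
Title: Simulation and Computational Modeling of Approach-Avoidance
    Decisions Under Threat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generative simulation of the Passive-active Approach-avoidance
    Task (PAT): factorial reward/threat schedules, anticipatory cardiac
    deceleration (bradycardia) traces, logistic choice agents, shifted
    log-normal response times, and probabilistic outcomes. Implements the
    trial-wise bradycardia index (delta-hr), the base and three
    freezing-state decision-value models (aversive value, value comparison,
    action invigoration) with pooled maximum-likelihood and hierarchical
    fitting, highest-density-interval inference, model comparison, parameter
    recovery, and construction of HRF-convolved model-based fMRI regressors
    from difference scores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
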