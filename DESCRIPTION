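Package: dyadstate
Title: Continuous-Time Markov Chain Analysis of Leadership in Foraging Dyads
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing leadership and following in pairs of
    animals moving between a safe covered area and a risky exposed area.
    Joint cover/exposure behaviour of a dyad is modelled as a fully
    observed four-state continuous-time Markov chain with log-linear
    covariate effects (satiation, boldness) on the transition
    intensities.  The package provides event-log input/output and
    validation, behavioural summaries (boldness scores, trip taxonomy,
    initiation and follow counts), maximum-likelihood estimation with
    Wald tests and confidence intervals, a seeded Gillespie simulator
    and synthetic-study generator with known ground truth, a paired
    t-test battery for pre/post-satiation contrasts, and a command-line
    pipeline tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
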