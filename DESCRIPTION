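Package: lbpcea
Title: Markov Cohort Cost-Effectiveness Model of Acupuncture Collaborative
    Care for Chronic Low Back Pain
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness model comparing usual care
    with usual care plus acupuncture (collaborative treatment) for chronic
    low back pain in South Korea. Implements a four-state quarterly Markov
    cohort model (acute LBP, chronic LBP, well, dead) with mortality-adjusted
    transition matrices, QALY and cost accumulation under configurable reward
    and discounting conventions, incremental cost-effectiveness and net
    monetary benefit analysis, Monte-Carlo probabilistic sensitivity analysis
    with cost-effectiveness acceptability curves, expected value of perfect
    information (per person and population), DerSimonian-Laird random-effects
    pooling of study-level risk ratios, and seed-reproducible generators for
    the externally sourced inputs (study-level recovery counts, life tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    ggplot2,
    withr,
    optparse
Config/testthat/edition: 3
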