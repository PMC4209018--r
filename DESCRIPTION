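Package: msmarkov
Title: Discrete-Time Markov Modelling of Metabolic Syndrome Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the natural history of metabolic syndrome (MS)
    from longitudinal health check-up data with a reversible 7-state
    discrete-time Markov model. Check-up records are classified into mutually
    exclusive metabolic states using the Chinese Diabetes Society (CDS)
    criteria; annual transition-probability matrices are estimated per
    sex/age stratum as the mean of consecutive-year incidence-rate matrices;
    state occupancy is projected over a 10-year horizon from any starting
    state and validated against empiric prevalence. A synthetic-cohort
    generator produces check-up records whose latent state dynamics follow a
    known ground-truth matrix, so the full pipeline is testable without
    access to hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
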