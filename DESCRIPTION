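Package: eaesim
Title: Spatially Resolved Agent-Based Simulation of Murine Experimental
    Autoimmune Encephalomyelitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lattice-based, discrete-time agent simulator of murine
    experimental autoimmune encephalomyelitis (EAE). Seven immune and neural
    cell populations interact as stochastic state machines across five
    networked two-dimensional tissue compartments carrying diffusing and
    decaying cytokine fields. Clinical 0-5 EAE scores are derived from
    neuronal-death rates by sliding-window smoothing and calibrated
    thresholding; episodes, relapses and mortality are extracted from the
    score series. The package ships four in-silico interventions (regulatory
    efficacy, Qa-1 expression duration, splenectomy and anti-CD3 TCR
    blockade), a nonparametric statistics toolkit (Vargha-Delaney A-test with
    effect-magnitude bands, Mann-Whitney U, Fisher's exact test, group
    summaries), one-at-a-time parameter robustness analysis with
    significant-deviation boundaries and rank tables, and a batch experiment
    runner with deterministic replicate seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    optparse
Config/testthat/edition: 3
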