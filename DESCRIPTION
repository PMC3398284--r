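Package: hemipool
Title: Competitive Fitness Profiling of Hemizygote Pools in Continuous Culture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of pooled competition experiments in
    chemostat and turbidostat cultures. Simulates hemizygote pools under
    replicator dynamics with multinomial sampling and multiplicative
    measurement noise, estimates per-strain modified flux control
    coefficients (FCC') by linear regression of log relative abundance on
    time, classifies haploinsufficient and haploproficient strains at a
    chosen false discovery rate, and provides downstream statistics:
    logistic-regression gene-set enrichment, hypergeometric overlap tests,
    cross-experiment Spearman correlation and clustering, and Dean-Jett-Fox
    fitting of DNA-content histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
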