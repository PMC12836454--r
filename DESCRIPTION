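Package: parawarm
Title: Temperature Effects on Host-Parasitoid Interactions, Diet Breadth
    and Phylogenetic Specialization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for factorial host-parasitoid rearing
    experiments run at several temperatures. Computes per-vial parasitism
    success and degree of infestation against unparasitized-control
    baselines, fits Bayesian multilevel binomial models with an optional
    phylogenetically correlated host effect (via JAGS) and reports
    temperature contrasts as median odds ratios with highest-posterior-
    density intervals and PSIS-LOO model comparison, quantifies parasitoid
    diet breadth as phylogenetic Hill diversity (order q) over replicate
    diversity sets with marginal-mean temperature contrasts and a
    replicate-shuffling sensitivity analysis, and measures phylogenetic
    specialization relative to host availability with the distance-based
    DSI* index and a Monte Carlo availability null. Includes a seeded
    synthetic-experiment generator that emulates the vial-level design so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    coda,
    emmeans,
    jsonlite,
    rjags,
    stats,
    tools,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
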