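Package: serialabc
Title: Serial Coalescent Simulation and Approximate Bayesian Computation
    for Time-Stamped Mitogenome Samples
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Demographic inference from serially sampled, non-recombining
    haploid sequence data (ancient and modern mitogenomes). Provides a
    serial-sampling coalescent simulator with finite-sites mutation for
    two-deme demographic models (Mesolithic continuity, Neolithic
    replacement, and admixture scenarios), a fixed panel of population
    summary statistics, partial-least-squares compression of the panel,
    approximate Bayesian computation model choice by weighted multinomial
    logistic regression, Beaumont-style local-linear parameter estimation
    after a logtan transformation, posterior-predictive fit diagnostics,
    and a pseudo-observed-data power study (true/false positive rates,
    parameter recovery and coverage). A synthetic-data generator produces
    observed-like study datasets with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    ape,
    nnet,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
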