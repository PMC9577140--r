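Package: avnodetrend
Title: Continuous ECG-Based Assessment of AV-Nodal Conduction During Atrial
    Fibrillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for continuous, non-invasive characterization of
    atrioventricular (AV) nodal refractoriness and conduction delay during
    atrial fibrillation from 24-hour RR-interval series and atrial
    fibrillatory rate (AFR) trends.  Implements an event-driven dual-pathway
    network model of the AV node, a Poincare-plot histogram fitness function,
    a problem-specific genetic algorithm that tracks time-varying model
    parameters across sliding data segments with adaptive effort, a
    variance-based (Sobol-type) local uncertainty estimate for each parameter
    set, and population-level cosinor linear mixed-effects analysis of
    circadian variation including drug comparisons.  A synthetic-cohort
    generator with known ground truth supports end-to-end validation without
    access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lme4,
    lhs,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
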