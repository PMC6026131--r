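Package: pialnet
Title: Topology and Count-Model Inference for Pial Arterial Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the topology of pial (leptomeningeal)
    arterial networks traced as planar graphs: seeded generation of
    synthetic cohorts with known ground truth, backbone/offshoot
    decomposition and loop counting, Voronoi territory assignment of
    penetrating arterioles with majority-area region rules, and Poisson
    mixed-effects count modelling with an area offset, including
    likelihood-ratio factor tests, Tukey-style post-hoc contrasts,
    overdispersion diagnostics and minimal-detectable-effect-size power
    computations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    xml2,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
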