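Package: latentpath
Title: Discovery and Analysis of Latent Carbon-Fixation Pathways in
    Metabolic Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for uncovering carbon-fixation pathways hidden in the
    metabolic network of a heterotrophic organism.  Implements
    thermodynamics-constrained mixed-integer enumeration of pathway
    supports (joint Max-min Driving Force / reaction-count objective with
    integer cuts and Pareto ranking), the Max-min Driving Force (MDF)
    linear program, curated flux-balance-analysis yield comparison of
    pathway variants, positional 13C atom-transition simulation of
    amino-acid isotopologue distributions, and Michaelis-Menten kinetics
    fitting, together with a self-contained central-metabolism fixture
    network carrying vendored transformed Gibbs energies so every stage
    runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
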