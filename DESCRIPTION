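Package: qdnet
Title: Quasi-Dynamic ODE Inference of Microbial Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs signed, weighted, directed microbial interaction
    networks from static (cross-sectional) abundance tables. Each sample's
    habitat index (total community abundance) replaces time as the dynamic
    axis: per-taxon allometric power laws link niche to habitat index,
    group-penalized regression selects each taxon's interaction partners,
    and a quasi-dynamic ODE system decomposes every taxon's abundance into
    an independent component and signed partner-dependent components.
    Includes functional clustering of taxa into modules, multilayer network
    assembly, ecological interaction-type and node-role classification, and
    a permutation likelihood-ratio test for comparing networks between
    contexts (e.g. diseased versus healthy guts). A synthetic-data generator
    with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    igraph,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
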