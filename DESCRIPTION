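Package: como
Title: Compound Optimization Monitor: Analog Series Diagnostics and
    Free-Wilson Design
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative diagnostics of chemical saturation and
    structure-activity relationship (SAR) progression for analog series in
    lead optimization, combined with Free-Wilson driven design and potency
    prediction of virtual analogs. Implements matched molecular pair (MMP)
    fragmentation and analog-series assembly on a lightweight SMILES
    molecular-graph layer, virtual analog enumeration in a normalized
    physicochemical reference space, the saturation (S), progression (P)
    and Free-Wilson neighborhood saturation (N) scores, additive
    Free-Wilson potency transfer over MMP networks, and ridge /
    Tanimoto-kernel support vector regression baselines with a double
    cross-validation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    withr,
    yaml
Config/testthat/edition: 3
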