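Package: grnlandscape
Title: Stochastic Potential Landscapes of a Cancer-EMT-Stemness Gene Regulatory Network
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Binding-site-resolved Gillespie simulation of a six-node gene
    regulatory circuit coupling cancer (P53/MDM2), epithelial-mesenchymal
    transition (ZEB/miR-200) and stemness (OCT4/miR-145) programs.
    Quantifies the Waddington potential landscape U = -ln P over marginal
    copy-number space, detects and labels attractor basins (normal,
    premalignant, cancer, stem cell, cancer stem cell, lesion, hyperplasia),
    computes minimax saddle barriers, mean first-passage times, path flux
    decompositions of normal-cancer routes, one-at-a-time sensitivity of
    barrier heights to regulation strengths, and a group-wise PCA comparison
    of synthetic expression mixtures against landscape attractors.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    cluster,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
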