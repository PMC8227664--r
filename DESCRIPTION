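Package: phytocommune
Title: Chemodiversity, Covariance Modules, and Tritrophic Path Models for
    LC-MS Metabolomics of Plant-Insect Communities
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the chemical-ecology analysis of untargeted LC-MS
    feature tables collected alongside insect community surveys: pseudospectrum
    quality control (retention-time/correlation grouping, ammonium-adduct
    removal, batch-effect filtering), compound-class annotation via the
    nitrogen rule, relative mass defect and Gaussian-mixture clustering with
    BIC model selection, internal-standard and dry-mass normalization,
    Hill-number chemodiversity, multivariate dispersion and PERMANOVA from
    first principles, unsigned weighted-correlation network modules with
    eigenvalue composite variables, and maximum-likelihood path models with
    effect decomposition. Includes a fully seeded synthetic-data generator
    that emulates a hierarchical two-site elevational field design so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
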