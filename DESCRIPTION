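Package: altripgls
Title: Phylogenetic Regression of Altriciality on Self-Control in Homeotherms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Two-stage phylogenetic generalized least squares (PGLS) analysis
    relating a residual-based degree of altriciality to cylinder-task
    self-control scores across 31 homeothermic species. Provides a PGLS
    engine with maximum-likelihood estimation of Pagel's lambda, phylogenetic
    variance-covariance machinery, residual diagnostics (standardized and
    studentized phylogenetic residuals, Q-Q data), Lilliefors normality
    statistics, the bundled species trait table and a reconstructed
    chronogram, plus a synthetic-data generator for parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    nlme,
    nortest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
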