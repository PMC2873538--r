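Package: emapimpute
Title: Symmetric Missing-Value Imputation for Epistatic Miniarray Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputation of missing values in symmetric gene-by-gene genetic
    interaction matrices (epistatic miniarray profiles, E-MAPs). Provides
    symmetric unweighted K-nearest-neighbour, correlation-weighted
    nearest-neighbour and symmetric local least squares imputers, together
    with simple baselines (zero fill, gene means, global median), an
    evaluation harness based on artificial masking (normalized RMSE,
    prediction correlation, three-class precision/recall/F1 with 20-fold
    cross-validation), a shared-annotation enrichment test for imputed
    interaction classes, a seeded generator of module-structured synthetic
    E-MAPs, and readers/writers for the tab-delimited flat-file formats
    used by E-MAP studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
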