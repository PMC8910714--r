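Package: podgp
Title: Age Estimation from Tooth Geometry Indicators via POD-Compressed
    Gaussian Process Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Surrogate ("metamodel") regression of chronological age, in
    months, of children and adolescents on a panel of 21 tooth- and
    bone-geometry indicators measured from panoramic dental radiographs.
    Indicator snapshots are compressed by proper orthogonal decomposition
    (POD) of the snapshot Gram matrix, and the truncated amplitude vectors
    are regressed on age with a Gaussian process using an automatic
    relevance determination (ARD) squared-exponential kernel whose
    hyperparameters are fitted by marginal-likelihood maximization.
    Includes truncation-level sweeps, train/test ratio studies, ARD
    sensitivity ranking of inputs, per-patient predictive uncertainty, a
    seeded synthetic-cohort generator for end-to-end testing, CSV/JSON
    persistence, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
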