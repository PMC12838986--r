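Package: breathstrat
Title: Electronic-Nose Breathprint Simulation and BI-RADS 4 Malignancy Risk Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates chemiresistive electronic-nose (eNose) breathprints as
    32-channel resistance time series with ambient, breath-capture and recovery
    phases; applies device quality-control criteria and cohort exclusion
    accounting; normalizes responses against the ambient baseline; trains a
    dual-input autoencoder-classifier that fuses the breathprint with its
    BI-RADS category under a composite, class-weighted loss with an extra
    false-negative penalty; and evaluates malignancy prediction by nested
    cross-validation with a conservative majority-vote ensemble, reporting
    per-subgroup sensitivity, specificity, NPV and PPV across repeated runs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
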