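Package: icushift
Title: Dataset-Shift Evaluation for ICU Prediction Models on Synthetic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates ICU cohorts with controllable context shifts and
    quantifies how clinical prediction models degrade under deployment
    barriers. Generates relational synthetic electronic-health-record
    cohorts (patients, stays, timestamped observations) with injectable
    temporal drift, population-subgroup effects and optional urine-output
    availability; labels acute kidney injury by the KDIGO creatinine and
    urine-output criteria and ICU readmission by time windows; trains
    multilayer-perceptron predictors including a layer-freezing transfer
    learning procedure; and evaluates AUROC loss under four deployment
    scenarios (temporal drift, change of features, data scarcity, change
    of population) with split-confounding diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
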