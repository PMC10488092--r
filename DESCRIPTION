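Package: puro2risk
Title: Intraoperative AKI Risk Modelling from Urine Oximetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating intraoperative acute kidney
    injury (AKI) risk models from noninvasive urine oximetry (PuO2) in
    cardiac surgery. Provides a synthetic-cohort generator emitting 1 Hz
    PuO2/urine-flow waveforms with surgical timelines and group-conditional
    demographics; artifact rejection and surgical-period segmentation for
    the waveforms (retrograde flow, stagnant urine, sensor error codes,
    low-flow discard, missingness rules); per-period hypoxia-exposure
    features (distribution summaries, time and area below PuO2 thresholds);
    forward stepwise logistic selection of preoperative features and
    AUROC-based selection of the best PuO2 feature; a bagged support vector
    machine classifier evaluated under leave-one-out cross-validation; and
    paired-model comparison statistics (DeLong test for correlated AUROCs,
    exact McNemar tests on sensitivity and specificity, Yates-corrected
    chi-square and pooled t univariate tables).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tools,
    e1071,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
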