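Package: ictalmetrics
Title: Engineered and Learned Seizure Biomarkers from Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for engineering and interpreting seizure biomarkers from
    single-channel, 1-second intracranial EEG epochs. Implements the classical
    metric set (Welch band powers, relative and log absolute band powers,
    energy ratio and epileptogenicity index, phase-locked high gamma, and
    Benford first-digit conformity via the Cho-Gaines distance in the time and
    frequency domains), two small neural feature encoders with a shared
    classifier trained under subject-wise leave-one-out cross-validation, a
    narrowband frequency-response probe for model interpretation, and
    random-forest Gini-importance feature selection with a leakage-guarded
    ensemble and deployment scheme. Includes a synthetic multi-subject iEEG
    generator so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
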