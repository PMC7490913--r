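Package: hisskit
Title: Hemorrhage Severity Scoring with Synthetic Patients, Expert
    Committees and Possibility Rule-Based Classification
Version: 0.1.0
Authors@R:
    person("HISS", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for developing and benchmarking the Hemorrhage Intensive
    Severity and Survivability (HISS) score, an ordinal 0-4 severity class
    fused from five biomarkers of hemorrhagic shock (glucose, lactate, pH,
    potassium and oxygen tension). Provides a rule-based generator of
    synthetic trauma biomarker panels seeded by hidden severity levels, a
    simulated multi-physician scoring committee with tunable intra- and
    inter-expert variability, label fusion by majority vote and by
    possibility histograms, a possibility rule-based classifier using
    function approximation (an evolving population of interval rules with
    linear per-class consequents), baseline classifiers (linear SVM, bagged
    decision trees, softmax neural network), cross-validation and
    learning-curve evaluation, one-way ANOVA model comparison, and a
    response-surface analysis predicting the patient and expert sample
    sizes required for a target accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
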