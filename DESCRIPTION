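Package: vavalid
Title: Validation Framework for Automated Verbal Autopsy Cause Assignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assigning causes of death from verbal autopsy (VA)
    questionnaires and for validating such methods. Implements the Tariff
    score classifier with bootstrap significance filtering, naive-Bayes
    symptom-pattern classifiers (a restricted-item joint-posterior variant
    and a one-vs-rest symptom-subset resampling variant), and King-Lu style
    direct estimation of cause-specific mortality fractions (CSMFs).
    Provides the uncorrelated train/test resampling design used to compare
    such methods (Dirichlet-drawn target cause compositions, disjoint death
    sets), per-cause sensitivity/specificity, chance-corrected concordance,
    Cohen's kappa, CSMF accuracy, CSMF regression diagnostics, head-to-head
    comparison tables, and a synthetic VA data generator with known
    cause-conditional endorsement structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    quadprog,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
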