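Package: ugibrisk
Title: Pre-Endoscopy Risk Scores for Upper Gastrointestinal Bleeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calculators for the Glasgow-Blatchford score (GBS), the modified
    GBS restricted to its quantitative factors, and the pre-endoscopy Rockall
    score, together with the statistical machinery used to evaluate them as
    triage instruments in upper gastrointestinal bleeding: tie-corrected
    Mann-Whitney ROC/AUC from grouped score counts, DeLong variance and paired
    AUC comparison, threshold diagnostics (sensitivity, specificity, predictive
    values), Youden-index cutoff selection, Woolf odds-ratio confidence
    intervals and Pearson chi-square tests on 2x2 tables, packaged grouped-count
    fixtures from a 590-patient emergency-department cohort, and a seeded
    two-latent-axis synthetic cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
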