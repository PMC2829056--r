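Package: liabilityAUC
Title: Genetic Interpretation of the Area Under the ROC Curve for
    Genomic Risk Profiles
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closed-form conversions under the liability-threshold model
    among disease prevalence, sibling recurrence risk, heritability of
    liability and the variance explained by a genomic profile, together
    with the maximum area under the ROC curve (AUC) attainable by a
    genetic risk predictor and its inversion to the proportion of genetic
    variance (or of sibling recurrence risk) explained. Also provides
    rank-based empirical AUC and ROC curves for scored case-control
    cohorts, a nuclear-family liability-threshold simulator for checking
    the analytic results, a batch report engine for disease parameter
    tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
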