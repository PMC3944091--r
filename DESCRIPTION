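Package: prolifsig
Title: Proliferation Markers Versus Commercial Gene Signatures for
    Node-Negative Breast Cancer Prognosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare the prognostic value of commercial-style
    gene-expression signatures against direct proliferation markers in
    lymph-node-negative breast cancer. Implements an Oncotype-DX-style
    21-gene recurrence score, MammaPrint-style risk classification by
    correlation to per-class average expression profiles and by
    two-cluster hierarchical clustering, ROC-based cut-off selection,
    supervised per-gene ANOVA selection with leave-one-out
    cross-validation and in-fold gene reselection, and Kaplan-Meier /
    log-rank / Cox proportional-hazards survival analysis of
    distant-metastasis-free survival. A synthetic cohort generator with
    a latent proliferation score, planted signature effects and
    right-censored exponential survival makes every stage testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
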