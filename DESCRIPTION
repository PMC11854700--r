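Package: ddhscreen
Title: Automated Quality Gating and Alpha-Angle Measurement for Infant Hip
    Ultrasound
Version: 0.1.0
Authors@R:
    person("Hana", "Sato", email = "hana.sato@example.org",
           role = c("aut", "cre"))
Description: Tools for automated screening of developmental dysplasia of the
    hip (DDH) on 2D B-mode ultrasound frames. Implements apex-point landmark
    estimation via a trainable heatmap model, signal-heterogeneity ridge
    extraction in the bone region (local-maximum filtering plus orthogonal
    least-squares ridge-line fitting), an iliac-verticality standard-plane
    quality gate (87-93 degrees), Graf alpha-angle measurement from the
    acetabular-roof ridge, and alpha-based DDH classification (alpha < 60
    degrees). Ships a synthetic B-mode phantom generator with speckle,
    reverberation and soft-tissue distractor artifacts that provides ground
    truth for every pipeline stage, plus ROC/AUC, sensitivity/specificity,
    pooled t-test and Benjamini-Hochberg evaluation utilities and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
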