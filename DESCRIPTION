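Package: MonoLR
Title: Monocyte/Lymphocyte-Ratio Biomarkers, Tumor Deconvolution and
    Phase II Survival Statistics for Immunoradiotherapy Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for translational analysis of immunoradiotherapy
    cohorts: windowing of longitudinal blood counts into treatment
    periods with per-cycle medians and monocyte/lymphocyte (MonoLR) and
    neutrophil/lymphocyte (NLR) ratios; construction of
    monocyte/macrophage marker signatures from differential-expression
    tables and non-negative least-squares deconvolution of bulk
    expression into cell-type scores; tumor myeloid/lymphoid ratio
    (MDCLR) surrogates from deconvolution scores and
    immunohistochemistry densities; ROC-based biomarker threshold
    selection by maximum positive likelihood ratio with
    training/validation splits; Kaplan-Meier estimation, logrank tests,
    hazard ratios, landmark rates with Wilson intervals, and the
    Fleming single-stage phase II design calculator; plus a seeded
    synthetic-cohort generator so the whole pipeline is testable
    without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
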