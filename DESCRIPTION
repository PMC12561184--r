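Package: dnbscore
Title: Dynamic Network Biomarkers and Cox-Weighted Risk Scores from
    Longitudinal Plasma Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects dynamic network biomarkers (DNBs) -- clusters of
    proteins whose cross-patient variance rises, intra-cluster correlation
    tightens and correlation with the rest of the network weakens during
    systemic therapy -- from longitudinal Olink-style NPX proteomics, and
    builds a Cox-weighted prognostic score (DNBscore) from the resulting
    panel. Includes supervised PLS-DA with VIP selection, the four DNB
    indices with a criticality-index ranking, survival stratification with
    Kaplan-Meier and Cox models, ROC-based response cutoffs, RECIST 1.1
    best-overall-response calling with trial efficacy and safety
    tabulation, 3+3 dose-escalation bookkeeping, a reference-anchored
    batch adjustment, and a synthetic cohort generator that reproduces the
    statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    e1071,
    cluster,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
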