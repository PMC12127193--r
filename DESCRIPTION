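Package: predstrat
Title: Predictive Biomarker Stratification for Randomized Trials with
    Targeted Plasma Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for post-hoc predictive-biomarker analysis of small
    randomized trials quantified by targeted multiple-reaction-monitoring
    mass spectrometry (MRM-MS). Covers transition-level quality control and
    absolute quantification from stable-isotope-standard peak-area ratios,
    clinical endpoint computation (percent change, EASI50 responder
    labels) with normality-gated testing, Youden-index-optimal cut-off
    stratification with direction selection, odds ratios with the
    Haldane-Anscombe zero-cell correction, positive and negative predictive
    values, logistic multi-marker combination search with
    predicted-probability thresholds, exploratory analytics (hierarchical
    clustering, PCA, volcano statistics, preranked gene-set enrichment with
    permutation significance), and a seeded synthetic trial generator so the
    whole pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    fgsea
Config/testthat/edition: 3
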