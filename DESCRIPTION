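Package: purimetrics
Title: Quantitative Analysis of Acute Hyperpurinergia in Mouse Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for characterizing the whole-body response to
    systemic extracellular ATP in mice. Covers targeted-metabolomics scoring
    (control-referenced log2 z-scores, Mann-Whitney and ANOVA/Fisher-LSD
    univariate statistics, Benjamini-Hochberg and Storey q multiplicity
    control, PLS-DA with variable-importance-in-projection scores, pathway
    impact ranking by summed VIP, and k-nearest-neighbor supercluster
    detection), indirect-calorimetry and thermoregulation metrics (RER,
    radiated heat, percent change, dose-response slope comparisons,
    phase-window temperature analysis), purinergic behavioral response scale
    (PBRS) scoring, mouse-to-human age equivalence, and CO2-normalized
    breathomics. Includes seeded synthetic-data generators that emulate the
    statistical structure of the study designs so every stage is testable
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
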