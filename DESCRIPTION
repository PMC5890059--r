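Package: ironmr
Title: Mendelian Randomisation of Prenatal Iron Status and Offspring
    Respiratory and Atopic Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weighted maternal genotypic risk scores for four iron biomarkers
    (serum iron, ferritin, transferrin, transferrin saturation) built from a
    published 12-SNP weight table, with instrument-validation statistics
    (Hardy-Weinberg likelihood-ratio test, pairwise dosage LD, haemoglobin
    proxy validation), one-sample score-outcome association models, the
    summary-data Mendelian randomisation estimators (inverse-variance
    weighted, MR-Egger, weighted median), and a collider-bias simulation
    study of stratification on iron supplementation.  A seeded synthetic
    mother-child cohort generator with the causal structure
    genotype -> iron status -> (haemoglobin, supplementation) -> offspring
    outcomes makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    lmtest,
    rlang,
    sandwich,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
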