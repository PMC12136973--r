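Package: dielomics
Title: Diurnal Multi-Omics Rhythmicity and Photoacclimation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for diurnal multi-omics time courses of
    light-acclimated, synchronized algal cultures. Implements fixed-period
    (24 h) cosinor rhythm detection with acrophase estimation and circular
    phase-concordance statistics, a simplified negative-binomial Wald test
    for transcript counts and a Z-score/limit-of-quantitation outlier
    procedure for protein fold changes, classification of core
    light-specific and constitutive responses with mRNA-protein lag
    concordance, merged k-means clustering with hypergeometric term
    enrichment and PCA/correlation quality control, and closed-form
    photophysiology indices (xanthophyll de-epoxidation state, thylakoid
    stacking repeat distance, Fv/Fm, NPQ, 77 K PSI/PSII fluorescence
    ratio). A synthetic-data generator produces multi-omics datasets with
    known ground truth so every stage can be validated without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
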