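Package: phosreg
Title: SILAC Phosphoproteomic Regulation Calling and BTK-Inhibitor Pharmacology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for characterizing a covalent BTK inhibitor:
    empirical-Gaussian-null regulation calling on label-swapped SILAC
    phosphoproteomics replicates (class-I site filtering, histogram Gaussian
    regression, +/- 2.5 sigma ratio thresholds, dual-replicate consistency),
    kinase-panel IC50 selectivity arithmetic with censored values, logistic
    dose-response fitting (4PL/2PL/sigmoid Emax) with confidence intervals,
    KINOMEscan percent-control hit calling, BioMAP annotation rules,
    microarray differential expression (75th-percentile normalization,
    Welch t, Benjamini-Hochberg) with gene-wise-permutation GSEA, 2^-ddCt
    qPCR quantification, and xenograft pharmacodynamic statistics (tumor
    growth inhibition, Dunnett many-to-one comparisons, dose-trend
    regression, MFI inhibition with viability exclusion). Includes seeded
    synthetic-data generators reproducing the statistical structure each
    stage assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    mvtnorm
Suggests:
    testthat (>= 3.0.0),
    withr,
    multcomp,
    fgsea,
    jsonlite
Config/testthat/edition: 3
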