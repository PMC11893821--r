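Package: CQRBatch
Title: Batch Effect Correction for Microbiome Count Data via Composite
    Quantile Regression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage batch effect correction for zero-inflated,
    over-dispersed microbiome OTU count tables. Stage one removes
    systematic (constant per-batch) effects by per-OTU negative binomial
    regression with batch fixed effects, followed by quantile mapping of
    the non-zero counts onto the batch-free distribution. Stage two
    removes nonsystematic (distributional) effects by modelling the
    zero-inflated conditional distribution of each OTU with a logistic
    presence model and composite quantile regression, then transporting
    every sample onto a data-driven reference batch selected by
    Kruskal-Wallis homogeneity screening and robust coefficient of
    variation. Includes a PERMANOVA / PCoA / silhouette evaluation suite
    over Bray-Curtis, Aitchison, Canberra and Manhattan dissimilarities,
    and a zero-inflated negative binomial simulator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    MASS,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    quantreg,
    cluster,
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Microbiome, BatchEffect, Normalization, Regression, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'CQRBatch-package.R'
    'cqr.R'
    'evaluate.R'
    'io.R'
    'nb-correction.R'
    'pipeline.R'
    'reference.R'
    'simulate.R'
    'zero-model.R'
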