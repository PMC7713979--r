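Package: seqeffort
Title: Sequencing-Effort Estimation for Metatranscriptomes and
    Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the sequencing depth needed to cover the gene
    richness of a complex microbial community. Simulates gene-by-sample
    count matrices under a Dirichlet-multinomial model, computes
    sample-size-based rarefaction and Chao1 extrapolation curves of gene
    richness, fits Weibull growth models to extrapolate the curve
    asymptote (the maximum number of detectable genes) with confidence
    bands, derives the read depths covering 90/95/99 percent of the
    asymptote and the resulting sampling-effort percentage, and trains
    regression predictors (stepwise linear, support-vector,
    gradient-boosting) that recover these quantities from roughly the
    first 20 percent of sequencing depth, with bagging prediction
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    MASS,
    e1071,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
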