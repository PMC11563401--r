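Package: mtgp
Title: Univariate and Multivariate Genomic Prediction for Multi-Environment Trials
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for genomic prediction in inbred crop panels evaluated in
    multi-condition field trials. Covers the full analysis chain: genotype
    quality control (minor-allele-frequency and missingness filters,
    recoding, mean imputation), genomic relationship and Gaussian-kernel
    matrices, stage-one mixed-model analysis of plot records (adjusted
    genotype means, broad-sense heritability, protein/yield deviation
    indices), genomic genetic correlations, univariate and multivariate
    GBLUP by REML, multitrait Bayesian ridge, spike-and-slab and
    reproducing-kernel-Hilbert-space regression by Gibbs sampling with
    missing-phenotype augmentation, a multivariate random forest with inner
    grid-search tuning, and masking-based cross-validation schemes (CV1/CV2)
    with Duncan multiple-range and Fisher z comparisons of prediction
    accuracy. A synthetic-trial generator with known genetic architecture
    supports testing and calibration of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    lme4,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
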