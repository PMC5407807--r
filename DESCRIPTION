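Package: BiDirMR
Title: Bi-Directional Mendelian Randomization with Genetic Risk Scores
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for bi-directional Mendelian randomization analysis of
    continuous traits instrumented by polygenic risk scores, motivated by
    the body-mass-index / serum-testosterone causal question in men.
    Provides an S4 container for per-cohort genotype dosages and
    phenotypes built on SummarizedExperiment; weighted and unweighted
    genetic risk score construction with explicit effect-allele
    harmonization and missing-data policies; covariate-adjusted Z-score
    standardization of phenotypes; instrument diagnostics (association
    R-squared, the F statistic, confounder balance, interaction and
    non-linearity checks, per-variant scans with Bonferroni flags);
    causal-effect estimation in both directions by the instrumental
    variable ratio and two-stage least squares, including SHBG-adjusted
    variants, an independent-instrument pleiotropy split, a Hausman-type
    observational-versus-IV comparison, and translation of standardized
    effects into percent change over a clinical BMI interval;
    fixed-effect and DerSimonian-Laird random-effects inverse-variance
    meta-analysis with heterogeneity statistics alongside pooled
    individual-level analysis; analytic and Monte-Carlo power for IV
    regression; and a multi-cohort synthetic data generator with a
    confounded linear structural model for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    yaml,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: StatisticalMethod, GenomeWideAssociation, SNP, Epidemiology
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'BiDirMR-package.R'
    'diagnostics.R'
    'io.R'
    'meta.R'
    'mr.R'
    'standardize.R'
    'scores.R'
    'simulate.R'
    'pipeline.R'
    'plots.R'
    'power.R'
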