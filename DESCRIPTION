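Package: pregsae
Title: Small-Area Estimation of Pregnancy-Related Mortality by County and
    Race/Ethnicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Three-stage small-area estimation of pregnancy-related death
    rates by county, racial and ethnic population, 5-year age band, and
    year. Stage 1 fits a hierarchical Poisson disease-mapping model (race
    and covariate fixed effects, Gaussian age effects, conditional
    autoregressive county effects, race-specific time trends) by penalized
    likelihood and simulates mortality-rate draws from a Gaussian
    approximation to the posterior at the mode. Stage 2 adjusts draws for
    misreporting of race/ethnicity on death certificates using
    classification ratios. Stage 3 calibrates the adjusted draws with a
    two-stage iterative proportional fitting algorithm so that race-specific
    estimates remain consistent with all-race county totals and with
    aggregate benchmarks. Summarization provides age-standardized rates,
    95% uncertainty intervals from draw percentiles, posterior-probability
    significance calls, small-population masking, percent changes, and
    county-change summaries. A synthetic-data module generates populations,
    true rates, Poisson deaths, certificate-race misreporting, and
    garbage-coded deaths with fully known parameters so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    igraph,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'synthetic.R'
    'preprocess.R'
    'model.R'
    'misclass.R'
    'raking.R'
    'summarize.R'
    'io.R'
    'pipeline.R'
    'evaluate.R'
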