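Package: mgwas
Title: Microbiome Genome-Wide Association Analysis with Two-Stage
    Covariate-Residualized Tests
Version: 0.1.0
Authors@R:
    person("mgwas", "developers", email = "mgwas@localhost", role = c("aut", "cre"))
Description: Tools for genome-wide association analysis of skin (or other
    body-site) microbiome features across cohorts and microenvironments:
    synthetic two-cohort study generation with planted effects, microbial
    feature construction (taxonomy aggregation, rarefaction, abundance and
    prevalence filtering, Spearman redundancy clustering, Bray-Curtis
    dissimilarity), variant quality control and genetic principal components,
    negative-binomial residual association tests for single taxa, a
    moment-matched distance-based pseudo-F test for community composition,
    microenvironment-wise fixed-effect meta-analysis with explicit
    significance rules, single-causal-variant Bayesian fine-mapping with 95
    percent credible sets, and two-sample Mendelian randomization with
    instrument filters and sensitivity verdicts.
License: GPL (>= 3)
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
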