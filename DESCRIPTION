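Package: delphiqi
Title: Delphi Consensus Statistics and a Hierarchical Quality Index for
    Evaluation Indicator Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and scoring multi-layer evaluation
    indicator systems with a competency-weighted Delphi process. Implements
    the per-indicator consensus statistics (mean, competency-weighted mean,
    full-mark rate, coefficient of variation), tie-corrected Kendall's
    coefficient of concordance with its chi-square test, importance/dispersion
    screening with cascade deletion over a three-layer indicator tree,
    weighted-mean-proportional weight normalisation, hierarchical score
    aggregation to an overall quality index, and psychometric validation of
    the resulting scale (Cronbach's alpha and a maximum-likelihood
    confirmatory factor analysis with absolute fit indices CMIN/df and SRMR).
    Includes seeded generators for expert panels, Likert rating tables and
    factor-structured item responses so every stage is testable without
    access to raw survey data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
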