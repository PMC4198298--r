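Package: progsig
Title: Prognostic Gene-Signature Scoring, Resampling Nulls and Co-Expression Coherence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives multi-cancer differential-expression gene signatures from
    paired normal/tumor cohorts (paired t-tests, Benjamini-Hochberg adjustment,
    accordant-direction selection across cancer types), builds Wald-weighted
    standardized risk scores from univariate Cox proportional-hazards fits,
    evaluates recurrence-free-survival separation (Kaplan-Meier, log-rank,
    multivariate Cox, stratified analyses), and assesses non-randomness of both
    prognostic power and co-expression coherence via resampling nulls over
    random same-size gene signatures, with a tree-ensemble regulatory-network
    coherence statistic. Includes seeded synthetic-data generators for paired
    and survival cohorts so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
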