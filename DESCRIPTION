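Package: pcnet
Title: Physician Collaboration Networks, Hospital Outcomes and
    Exponential Random Graph Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds per-hospital physician collaboration networks (PCNs)
    from patient-visit claims records by bipartite projection (a tie
    between two physicians counts the hospitalised patients they both
    visited), computes Freeman degree and betweenness centralisation and
    network density, derives hospital outcome measures (mean
    hospitalisation cost per patient, readmission rate, mean patient
    age), and relates network structure to outcomes through rank
    correlations, simple and age-moderated regressions and extreme-group
    comparisons.  Includes an exponential random graph model (ERGM)
    engine for undirected networks with Markov (edge, k-star, triangle)
    and alternating (k-star, k-triangle, independent two-path)
    statistics, a Metropolis single-dyad-toggle sampler, and stochastic
    approximation (Robbins-Monro) Monte Carlo maximum likelihood
    estimation with convergence t-ratios and parameter t-values, plus a
    synthetic claims generator with tunable network centralisation and
    planted cost and readmission effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
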