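Package: underdx
Title: Bayesian Logistic Regression with an Underreported Binary Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the association between a binary exposure and
    a binary outcome when the exposure is underreported in administrative
    records, as for schizophrenia in health-care claims. Implements a Bayesian
    logistic regression with latent-truth data augmentation (Metropolis-within-
    Gibbs), perfect specificity and a beta-prior sensitivity model; prior
    elicitation for prevalence and diagnostic sensitivity by mean and effective
    sample size; a classical maximum-likelihood comparator; a seeded synthetic
    claims-cohort generator; and descriptive cohort summaries with chi-square
    and Kruskal-Wallis tests. Results are returned as tibbles with broom-style
    tidiers and ggplot2 plotting methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
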