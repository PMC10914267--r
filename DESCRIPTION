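Package: harvestprob
Title: Probabilistic Genotype Recommendation for Multi-Harvest Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bayesian and frequentist analysis of perennial multi-harvest
    variety trials.  Fits hierarchical linear models with homogeneous or
    per-harvest heterogeneous residual variances by a blocked Gibbs sampler
    with half-Cauchy hyperpriors on all scale parameters, provides
    convergence and fit diagnostics (split R-hat, WAIC with the variance
    penalty, posterior predictive p-values, highest posterior density
    intervals), and turns posterior draws into counting probabilities of
    superior performance and superior stability, marginally, pairwise and
    within harvests.  A frequentist REML/BLUP baseline with per-harvest
    residual variances, likelihood-ratio tests, a persistence index and
    Spearman rank comparisons completes the workflow, together with a
    ground-truth trial simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmmTMB,
    jsonlite,
    lme4,
    stats,
    tools,
    utils
Suggests:
    coda,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
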