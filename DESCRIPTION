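Package: pmimeta
Title: Frequentist and Bayesian Evidence Synthesis for Periprocedural
    Myocardial Infarction Definitions After CABG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for study-level evidence synthesis comparing competing
    definitions of periprocedural myocardial infarction (PMI) after coronary
    artery bypass grafting. Implements DerSimonian-Laird random-effects
    pooling of log hazard ratios and logit prevalences with heterogeneity
    statistics (Q, tau-squared, I-squared), Egger's regression test for
    small-study effects, the Altman-Bland interaction test between pooled
    effects, a Bayesian hierarchical normal-normal random-effects model with
    a normal prior on the pooled log hazard ratio and an inverse-gamma prior
    on the heterogeneity standard deviation (deterministic quadrature with an
    MCMC cross-check), posterior threshold-exceedance probabilities and Bayes
    factors with evidence classification, Wan's conversions from medians and
    quartiles or ranges to means and standard deviations, reconstruction of
    individual patient data from digitized Kaplan-Meier curves with
    numbers-at-risk (Guyot-family interval solver) followed by univariable
    Cox regression, synthetic-data generators emulating the assumed data
    model, and a config-driven pipeline producing a structured report.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
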