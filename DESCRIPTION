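Package: auxbias
Title: Bias Amplification from Auxiliary Variables in Multiple Imputation
    under MNAR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the additional bias of the multiple-imputation (MI)
    estimator that arises when an auxiliary variable predicting missingness,
    but not the missing values themselves, is added to the imputation model
    while data are missing not at random (MNAR). Provides exact closed-form
    expressions for the limiting (maximum) bias, additional bias, and bias
    amplification factor under latent-normal missingness path models; an
    independent population partial-regression oracle built from the implied
    joint covariance; a synthetic-data generator for the supported causal
    scenarios (continuous or dichotomised outcome/exposure); a proper
    multiple-imputation engine with Rubin's-rules pooling and a
    complete-records comparator; and Monte-Carlo study runners that verify
    the algebra by simulation, including limiting-case convergence checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
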