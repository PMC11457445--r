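#' Closed-form limiting bias of the MI estimator
#'
#' As the proportion of missing values tends to one, the expected value of
#' the MI estimator of the exposure coefficient tends to the population
#' coefficient from a regression that additionally conditions on the latent
#' missingness score `R` (and on the auxiliary variable `Z` when `Z` is in
#' the imputation model). `bias_summary()` evaluates these limits exactly
#' from the direct effect sizes and error variances of a scenario and reports
#' the associated bias measures:
#'
#' * `max_bias` — limiting coefficient without `Z` minus the true value;
#' * `max_additional_bias` — change in the limit from adding `Z`;
#' * `max_total_bias` — their sum;
#' * `max_relative_additional_bias` — additional bias as a percentage of the
#'   true coefficient (`NA` when the true coefficient is zero: the relative
#'   measure is undefined there, never silently `NaN`);
#' * `amplification_factor` — ratio of the bias with `Z` to the bias without.
#'
#' `bias_summary()` dispatches on the scenario: [bias_s1_outcome()] for S1
#' (outcome incomplete, missingness caused by the outcome),
#' [imputation_coef_bias_s2()] for S2 with the exposure incomplete (the bias
#' is in the imputation-model coefficient of `Y` and is away from zero, the
#' opposite orientation to S1), and [bias_s3_outcome()] for S3 with the
#' outcome incomplete (missingness caused by outcome and exposure; the bias
#' may be towards or away from zero but the auxiliary always amplifies it).
#' For S2 with the outcome incomplete both MI estimators are unbiased and
#' every bias measure is zero.
#'
#' @param spec A [scenario_spec()].
#' @return A one-row tibble with columns `scenario_id`, `beta_true`,
#'   `coef_limit_no_aux`, `coef_limit_with_aux`, `max_bias`,
#'   `max_additional_bias`, `max_total_bias`, `max_relative_additional_bias`
#'   (percent), `amplification_factor`.
#' @examples
#' bias_summary(scenario_spec("S1", beta_YX = 1, beta_RY = 1, beta_RZ = 1))
#' @export
bias_summary <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  switch(spec$scenario_id,
    S1 = bias_s1_outcome(spec),
    S2_X = imputation_coef_bias_s2(spec),
    S2_Y = bias_s2_outcome_unbiased(spec),
    S3_Y = bias_s3_outcome(spec),
    S3_X = rlang::abort(
      paste(
        "No closed form is available for the MI estimator itself when the",
        "exposure is incomplete in S3; use imputation_coef_additional_bias_s3()",
        "for the imputation-model coefficient, or run_mc_study() for the",
        "estimator."
      ),
      class = "auxbias_spec_error"
    )
  )
}

new_bias_summary <- function(scenario_id, beta_true, coef_no, coef_with,
                             amplification_factor) {
  max_bias <- coef_no - beta_true
  max_additional <- coef_with - coef_no
  tibble::tibble(
    scenario_id = scenario_id,
    beta_true = beta_true,
    coef_limit_no_aux = coef_no,
    coef_limit_with_aux = coef_with,
    max_bias = max_bias,
    max_additional_bias = max_additional,
    max_total_bias = coef_with - beta_true,
    max_relative_additional_bias =
      if (beta_true == 0) NA_real_ else 100 * max_additional / beta_true,
    amplification_factor = amplification_factor
  )
}

#' Limiting bias when the outcome causes its own missingness (S1)
#'
#' Both limiting coefficients shrink the true `beta_YX` by a factor
#' `1 - beta_RY^2 var_Y / (beta_RY^2 var_Y + beta_RZ^2 var_Z + var_R)`
#' (imputation model without `Z`) or
#' `1 - beta_RY^2 var_Y / (beta_RY^2 var_Y + var_R)` (with `Z`): the MI
#' estimator is biased towards zero and adding the auxiliary removes the
#' `beta_RZ^2 var_Z` term from the denominator, amplifying the shrinkage by
#' `1 + beta_RZ^2 var_Z / (beta_RY^2 var_Y + var_R)`.
#'
#' @inheritParams bias_summary
#' @inherit bias_summary return
#' @export
bias_s1_outcome <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$scenario_id != "S1") {
    rlang::abort("bias_s1_outcome() requires scenario S1.",
                 class = "auxbias_spec_error")
  }
  num <- spec$beta_RY^2 * spec$var_Y
  den0 <- num + spec$var_R
  denZ <- den0 + spec$beta_RZ^2 * spec$var_Z
  coef_no <- spec$beta_YX * (1 - num / denZ)
  coef_with <- spec$beta_YX * (1 - num / den0)
  amp <- 1 + spec$beta_RZ^2 * spec$var_Z / den0
  new_bias_summary("S1", spec$beta_YX, coef_no, coef_with, amp)
}

#' Limiting bias when outcome and exposure cause missingness (S3, outcome incomplete)
#'
#' The limiting bias without the auxiliary is
#' `-beta_YX * beta_RY * var_Y * (beta_RY + beta_RX / beta_YX) /
#'  (beta_RY^2 var_Y + var_R + beta_RZ^2 var_Z)`,
#' evaluated here with the numerator expanded to
#' `-beta_RY * var_Y * (beta_YX * beta_RY + beta_RX)` so that `beta_YX = 0`
#' is handled without a 0/0. The bias may be towards or away from zero
#' depending on the sign of `beta_RY + beta_RX / beta_YX`, but the additional
#' bias from adding `Z` is always in the same direction, with the same
#' amplification factor as in S1.
#'
#' @inheritParams bias_summary
#' @inherit bias_summary return
#' @export
bias_s3_outcome <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$scenario_id != "S3_Y") {
    rlang::abort("bias_s3_outcome() requires scenario S3_Y.",
                 class = "auxbias_spec_error")
  }
  den0 <- spec$beta_RY^2 * spec$var_Y + spec$var_R
  denZ <- den0 + spec$beta_RZ^2 * spec$var_Z
  num <- spec$beta_RY * spec$var_Y * (spec$beta_YX * spec$beta_RY + spec$beta_RX)
  max_bias <- -num / denZ
  max_additional <- -num * spec$beta_RZ^2 * spec$var_Z / (denZ * den0)
  amp <- 1 + spec$beta_RZ^2 * spec$var_Z / den0
  new_bias_summary(
    "S3_Y", spec$beta_YX,
    coef_no = spec$beta_YX + max_bias,
    coef_with = spec$beta_YX + max_bias + max_additional,
    amplification_factor = amp
  )
}

# S2 with the outcome incomplete: CRA and both MI estimators are unbiased for
# a continuous outcome, so every bias measure is identically zero.
bias_s2_outcome_unbiased <- function(spec) {
  new_bias_summary("S2_Y", spec$beta_YX,
                   coef_no = spec$beta_YX, coef_with = spec$beta_YX,
                   amplification_factor = 1)
}

#' Limiting bias of the imputation-model Y coefficient (S2, exposure incomplete)
#'
#' When the exposure `X` is incomplete and missingness is related to the
#' outcome only through the unmeasured `U`, the imputation model regresses
#' `X` on `Y` (and possibly `Z`). The limiting `Y` coefficient inflates the
#' true reverse-regression coefficient `beta_XY = Cov(X, Y) / Var(Y)` by
#' `1 / (1 - rho^2)` where `rho^2` is the squared correlation of `Y` with the
#' part of `R` not explained by the conditioning set; adding `Z` shrinks the
#' residual variance of `R` and inflates further, so the bias here is away
#' from zero — the opposite orientation to S1.
#'
#' `beta_XY` is computed from the implied joint covariance rather than asked
#' of the user, since it is a derived quantity.
#'
#' @inheritParams bias_summary
#' @inherit bias_summary return
#' @export
imputation_coef_bias_s2 <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$scenario_id != "S2_X") {
    rlang::abort("imputation_coef_bias_s2() requires scenario S2_X.",
                 class = "auxbias_spec_error")
  }
  var_y_marg <- spec$beta_YX^2 * spec$var_X + spec$beta_YU^2 * spec$var_U +
    spec$var_Y
  beta_xy <- spec$beta_YX * spec$var_X / var_y_marg
  A <- spec$beta_YU^2 * spec$beta_RU^2 * spec$var_U^2
  dZ <- spec$beta_RZ^2 * spec$var_Z + spec$beta_RU^2 * spec$var_U + spec$var_R
  d0 <- spec$beta_RU^2 * spec$var_U + spec$var_R
  a_no <- A / (var_y_marg * dZ)   # squared Y-R correlation given (X-free) set
  a_with <- A / (var_y_marg * d0)
  coef_no <- beta_xy / (1 - a_no)
  coef_with <- beta_xy / (1 - a_with)
  # amplification = ratio of the inflation-induced biases; 1 when the MNAR
  # pathway is severed (A = 0) and there is no bias to amplify
  amp <- if (A == 0) 1 else (a_with * (1 - a_no)) / (a_no * (1 - a_with))
  new_bias_summary("S2_X", beta_xy, coef_no, coef_with, amp)
}

#' Maximum additional bias of the imputation-model Y coefficient (S3, exposure incomplete)
#'
#' Evaluates the exact closed-form expression for the limiting change in the
#' `Y` coefficient of the imputation model for `X` when `Z` is added, under
#' the diagram in which both outcome and exposure cause missingness. The
#' expression is the product of `beta_XY * beta_RX`, a bracket mixing the
#' `Y`- and `X`-pathways into `R`, and the difference of two reciprocals of
#' residual variances of `R` (with and without `Z` in the conditioning set).
#' The term `beta_XY * beta_RY * var_Y / beta_YX` is evaluated in its
#' algebraically equivalent form `beta_RY * var_Y * var_X / Var(Y)` so that
#' `beta_YX = 0` does not produce a 0/0.
#'
#' @inheritParams bias_summary
#' @return A single number: the maximum additional bias of the `Y`
#'   coefficient in the imputation model for `X`.
#' @export
imputation_coef_additional_bias_s3 <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$scenario_id != "S3_X") {
    rlang::abort("imputation_coef_additional_bias_s3() requires scenario S3_X.",
                 class = "auxbias_spec_error")
  }
  var_y_marg <- spec$beta_YX^2 * spec$var_X + spec$var_Y
  beta_xy <- spec$beta_YX * spec$var_X / var_y_marg
  shrink <- 1 - spec$beta_YX^2 * spec$var_X / var_y_marg  # = var_Y / Var(Y)
  k <- spec$beta_YX^2 * spec$beta_RX^2 * spec$var_X^2 / var_y_marg
  dZ <- spec$beta_RX^2 * spec$var_X + spec$beta_RZ^2 * spec$var_Z +
    spec$var_R - k
  d0 <- spec$beta_RX^2 * spec$var_X + spec$var_R - k
  if (dZ <= 0 || d0 <= 0) {
    rlang::abort(
      "Degenerate variance combination: residual variance of R is non-positive.",
      class = "auxbias_numeric_error"
    )
  }
  bracket <- spec$beta_RY * spec$var_Y * spec$var_X / var_y_marg +
    beta_xy * spec$beta_RX * spec$var_X * shrink
  spec$beta_RX * bracket * (1 / dZ - 1 / d0)
}

#' Logistic/probit coefficient conversions
#'
#' `logistic_to_probit()` applies the standard approximate conversion of a
#' logistic-regression coefficient to the equivalent probit (latent-normal)
#' coefficient, multiplying by 0.6. `probit_to_odds_ratio()` inverts it,
#' returning the odds ratio `exp(coef / 0.6)` implied by a probit-scale
#' coefficient.
#'
#' @param coef Coefficient (vectorised).
#' @return Numeric vector of the same length.
#' @examples
#' logistic_to_probit(-0.39) # ~ -0.23
#' probit_to_odds_ratio(0.5) # ~ 2.3
#' @export
logistic_to_probit <- function(coef) 0.6 * coef

#' @rdname logistic_to_probit
#' @export
probit_to_odds_ratio <- function(coef) exp(coef / 0.6)

#' Bias amplification factor from observable quantities
#'
#' The working form of the S1 amplification factor used with estimates from
#' real data, under the normalisation that the latent missingness score `R`
#' has mean 0 and variance 1 (which costs no generality):
#' `1 + beta_RZ^2 var_Z / (1 - beta_RZ^2 var_Z - (beta_RY * beta_YX)^2 var_X)`.
#' `beta_RZ` and the product `beta_RY * beta_YX` are typically obtained by
#' multiplying by 0.6 the auxiliary- and exposure-coefficients from a
#' logistic regression of the missingness indicator on auxiliary, exposure
#' and confounders ([logistic_to_probit()]); the two squared terms are then
#' the squared correlations of the auxiliary and the exposure with
#' missingness.
#'
#' @param beta_RZ Probit-scale coefficient of the auxiliary variable on
#'   missingness.
#' @param var_Z Variance of the auxiliary variable.
#' @param beta_RY_times_beta_YX Product of the outcome-on-missingness and
#'   exposure-on-outcome probit-scale coefficients (estimable as the
#'   probit-scale exposure coefficient in the missingness regression).
#' @param var_X Variance of the exposure.
#' @return The amplification factor (a number `>= 1` here, since under the
#'   unit-variance normalisation the denominator is a residual variance).
#' @examples
#' amplification_from_observed(-0.23, 0.18, 0.26, 0.25) # ~ 1.0098, i.e. ~1%
#' @export
amplification_from_observed <- function(beta_RZ, var_Z,
                                        beta_RY_times_beta_YX, var_X) {
  num <- beta_RZ^2 * var_Z
  den <- 1 - num - beta_RY_times_beta_YX^2 * var_X
  if (den <= 0) {
    rlang::abort(
      paste(
        "Non-positive denominator: the squared correlations with missingness",
        "exceed 1, violating the unit-variance normalisation of the latent",
        "score R."
      ),
      class = "auxbias_numeric_error"
    )
  }
  1 + num / den
}
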