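#' Exact large-sample expectation of the MI estimator at finite missingness
#'
#' The closed-form limits in [bias_summary()] hold as the missing proportion
#' tends to one; at a finite observed proportion `pi_obs` the MI estimator
#' conditions on the truncation event `R <= r`, not on `R = r`, and its
#' expectation can be computed exactly from truncated multivariate-normal
#' moments. Writing each variable as its projection on the latent score `R`
#' plus an independent residual, one-sided truncation of `R` shifts every
#' group mean by `a_V * (E[R | group] - mu_R)` and shrinks every covariance
#' by `a_V * a_W * (Var(R) - Var(R | group))`, with `a_V = Cov(V, R) /
#' Var(R)` and the standard truncated-normal mean/variance for `R` in each
#' group. The imputation model fitted on the observed group converges to the
#' observed-group projection of `Y` on its predictors; substituting its
#' coefficients into the missing group and recombining the two groups by the
#' law of total covariance yields the large-sample completed-data slope of
#' `Y` on `X` — the expectation the Monte-Carlo studies should reproduce at
#' any `pi_obs`, and which tends to the limiting coefficients as
#' `pi_obs` tends to zero.
#'
#' Available for scenarios with a continuous incomplete outcome (S1, S2_Y,
#' S3_Y). For S2_Y it returns `beta_YX` at every `pi_obs` — the
#' unbiasedness-despite-MNAR result in exact form.
#'
#' @param spec A [scenario_spec()] with `Y` incomplete and continuous.
#' @param include_aux Is the auxiliary `Z` in the imputation model?
#' @return The expected completed-data coefficient of `X` (a single number).
#' @examples
#' spec <- scenario_spec("S1", beta_YX = 1, beta_RY = 1, beta_RZ = 1,
#'                       pi_obs = 0.02)
#' expected_mi_coef(spec)                     # ~0.714, not yet 2/3
#' expected_mi_coef(spec, include_aux = TRUE) # ~0.600, not yet 1/2
#' @export
expected_mi_coef <- function(spec, include_aux = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$incomplete_var != "y" || spec$y_type != "continuous") {
    rlang::abort(
      "Finite-missingness expectations require a continuous incomplete Y.",
      class = "auxbias_spec_error"
    )
  }
  jc <- build_joint_covariance(spec)
  S <- jc$cov
  mu <- jc$means
  pi1 <- spec$pi_obs
  if (pi1 == 1) {
    return(S["y", "x"] / S["x", "x"])
  }

  # standardised truncated-normal moments of R in the observed (R <= r) and
  # missing (R > r) groups; the same 1 + c*m - m^2 variance form covers both
  cc <- stats::qnorm(pi1)
  m_obs <- -stats::dnorm(cc) / pi1
  m_mis <- stats::dnorm(cc) / (1 - pi1)
  v_obs <- 1 + cc * m_obs - m_obs^2
  v_mis <- 1 + cc * m_mis - m_mis^2

  vars <- c("x", "z", "y")
  var_r <- S["r", "r"]
  a <- S[vars, "r"] / var_r
  group <- function(m_g, v_g) {
    shift <- sqrt(var_r) * m_g
    list(
      mean = mu[vars] + a * shift,
      cov = S[vars, vars] - outer(a, a) * var_r * (1 - v_g)
    )
  }
  obs <- group(m_obs, v_obs)
  mis <- group(m_mis, v_mis)

  preds <- if (include_aux) c("x", "z") else "x"
  b <- solve(obs$cov[preds, preds], obs$cov[preds, "y"])
  b0 <- obs$mean["y"] - sum(b * obs$mean[preds])

  # completed data: true Y in the observed group, imputed mean structure in
  # the missing group; recombine with the law of total (co)variance
  ystar_mean_mis <- b0 + sum(b * mis$mean[preds])
  cov_ystar_x_mis <- sum(b * mis$cov[preds, "x"])
  dx <- obs$mean["x"] - mis$mean["x"]
  dy <- obs$mean["y"] - ystar_mean_mis
  cov_tot <- pi1 * obs$cov["y", "x"] + (1 - pi1) * cov_ystar_x_mis +
    pi1 * (1 - pi1) * dy * dx
  var_tot <- pi1 * obs$cov["x", "x"] + (1 - pi1) * mis$cov["x", "x"] +
    pi1 * (1 - pi1) * dx^2
  unname(cov_tot / var_tot)
}
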