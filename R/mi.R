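# Fast least-squares on a design matrix with intercept already included.
# Returns what proper imputation needs: coefficients, residual variance and
# the estimated sampling covariance of the coefficients.
fast_ols <- function(X, y) {
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    rlang::abort(
      "Design matrix is rank deficient; predictors are collinear.",
      class = "auxbias_fit_error"
    )
  }
  coefs <- qr.coef(qr_X, y)
  resid <- y - X %*% coefs
  df <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / df
  XtX_inv <- chol2inv(qr.R(qr_X))
  list(
    coefficients = drop(coefs),
    residual_variance = sigma2,
    coef_covariance = sigma2 * XtX_inv,
    df = df
  )
}

fast_logistic <- function(X, y) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial())
  )
  if (!fit$converged || any(abs(fit$coefficients) > 20)) {
    rlang::abort(
      paste(
        "Logistic fit failed to converge or shows perfect separation",
        "(a coefficient diverged); the observed records separate the classes."
      ),
      class = "auxbias_fit_error"
    )
  }
  # asymptotic covariance from the weighted cross-product of the design
  W <- fit$weights
  cov <- chol2inv(chol(crossprod(X * sqrt(W))))
  list(
    coefficients = fit$coefficients,
    residual_variance = NA_real_,
    coef_covariance = cov,
    df = length(y) - ncol(X)
  )
}

# single draw from N(mean, cov) via the Cholesky factor
draw_mvnorm <- function(mean, cov) {
  L <- chol((cov + t(cov)) / 2)
  drop(mean + t(L) %*% stats::rnorm(length(mean)))
}

#' Fit the imputation model to the observed records
#'
#' Regresses the incomplete variable on `predictors` using only records with
#' `r_ind = 1`: ordinary least squares when the incomplete variable is
#' continuous, maximum-likelihood logistic regression when it is binary.
#' `U` (the unmeasured variable) and the latent score are never admissible
#' predictors.
#'
#' @param data A [simulate_scenario()] result.
#' @param predictors Character vector drawn from `c("x", "y", "z")`,
#'   excluding the incomplete variable itself.
#' @return An object of class `imputation_model_fit`: coefficients (intercept
#'   first), `residual_variance` (linear family only), `coef_covariance`,
#'   `family`, `predictors`, `response`, `n_obs` and residual `df`.
#' @export
fit_imputation_model <- function(data, predictors) {
  spec <- dataset_spec(data)
  response <- spec$incomplete_var
  allowed <- setdiff(c("x", "y", "z"), response)
  if (length(predictors) == 0 || !all(predictors %in% allowed)) {
    rlang::abort(
      sprintf("`predictors` must be drawn from {%s}.",
              paste(allowed, collapse = ", ")),
      class = "auxbias_fit_error"
    )
  }
  obs <- data$r_ind == 1L
  if (sum(obs) < length(predictors) + 2L) {
    rlang::abort("Too few observed records to fit the imputation model.",
                 class = "auxbias_fit_error")
  }
  X <- cbind(1, as.matrix(data[obs, predictors, drop = FALSE]))
  colnames(X) <- c("(Intercept)", predictors)
  y <- data[[response]][obs]
  family <- if ((response == "y" && spec$y_type == "binary") ||
                (response == "x" && spec$x_type == "binary")) {
    "logistic"
  } else {
    "linear"
  }
  fit <- if (family == "linear") fast_ols(X, y) else fast_logistic(X, y)
  structure(
    c(fit, list(family = family, predictors = predictors,
                response = response, n_obs = sum(obs))),
    class = "imputation_model_fit"
  )
}

#' Impute the missing values once, properly
#'
#' Produces one completed vector of the incomplete variable by drawing from
#' the fitted model's predictive distribution after perturbing its
#' parameters. Linear family: the residual variance is drawn from its scaled
#' inverse chi-square posterior (`sigma*^2 = sigma_hat^2 * df / chisq_df`),
#' the coefficients from `N(beta_hat, (sigma*^2 / sigma_hat^2) * V_beta)`,
#' and each missing value as its linear predictor plus `N(0, sigma*^2)`
#' noise. Logistic family: coefficients from the asymptotic normal
#' approximation `N(beta_hat, V_beta)`, then Bernoulli draws at the
#' inverse-logit probabilities. Observed values pass through untouched.
#'
#' The `perturb` and `noise` switches exist as testing hooks; both default on
#' (proper imputation) and suppressing them degenerates the draw to the
#' fitted conditional mean.
#'
#' @param fit A [fit_imputation_model()] result.
#' @param data The dataset the fit came from.
#' @param seed Integer seed.
#' @param perturb Draw new model parameters first?
#' @param noise Add residual noise (linear) / binomial noise (logistic)?
#' @return Numeric vector of length `nrow(data)`: the completed variable.
#' @export
draw_and_impute <- function(fit, data, seed, perturb = TRUE, noise = TRUE) {
  stopifnot(inherits(fit, "imputation_model_fit"))
  completed <- data[[fit$response]]
  miss <- data$r_ind == 0L
  if (!any(miss)) {
    return(completed)
  }
  set.seed(as.integer(seed))
  X_mis <- cbind(1, as.matrix(data[miss, fit$predictors, drop = FALSE]))
  if (fit$family == "linear") {
    sigma2_star <- if (perturb) {
      fit$residual_variance * fit$df / stats::rchisq(1, fit$df)
    } else {
      fit$residual_variance
    }
    beta_star <- if (perturb) {
      draw_mvnorm(fit$coefficients,
                  (sigma2_star / fit$residual_variance) * fit$coef_covariance)
    } else {
      fit$coefficients
    }
    mu <- drop(X_mis %*% beta_star)
    completed[miss] <- if (noise) {
      mu + stats::rnorm(sum(miss), 0, sqrt(sigma2_star))
    } else {
      mu
    }
  } else {
    beta_star <- if (perturb) {
      draw_mvnorm(fit$coefficients, fit$coef_covariance)
    } else {
      fit$coefficients
    }
    p <- stats::plogis(drop(X_mis %*% beta_star))
    completed[miss] <- if (noise) stats::rbinom(sum(miss), 1L, p) else p
  }
  completed
}

# Rubin's rules: pooled point estimate is the mean of the per-imputation
# estimates; pooled variance adds the finite-m inflated between component
rubin_pool <- function(estimates, variances) {
  m <- length(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  list(
    m = m,
    pooled_estimate = mean(estimates),
    within_variance = W,
    between_variance = B,
    pooled_variance = W + (1 + 1 / m) * B
  )
}

# analysis model: coefficient of x from a regression of y on x,
# linear for continuous y, logistic for binary y
analysis_fit <- function(y, x, binary_y) {
  X <- cbind(1, x)
  fit <- if (binary_y) fast_logistic(X, y) else fast_ols(X, y)
  c(estimate = unname(fit$coefficients[2]),
    variance = fit$coef_covariance[2, 2])
}

#' Multiple imputation estimate of the exposure coefficient
#'
#' Runs the full MI pipeline on one dataset: fit the imputation model to the
#' observed records, produce `m` independently drawn completed datasets
#' ([draw_and_impute()]), fit the analysis model — the regression of `Y` on
#' `X`, linear for a continuous outcome and logistic for a binary one — to
#' each, and pool by Rubin's rules: the pooled estimate is the mean of the
#' per-imputation estimates and the pooled variance is
#' `W + (1 + 1/m) * B`, with `W` the mean within-imputation variance and `B`
#' the between-imputation variance. With a single incomplete variable one
#' regression draw is a valid draw from the joint predictive distribution,
#' so no chained-equations iterations are run.
#'
#' @param data A [simulate_scenario()] result.
#' @param imputation_predictors Predictors for the imputation model (e.g.
#'   `"x"` or `c("x", "z")` when `Y` is incomplete).
#' @param m Number of imputations, at least 2.
#' @param seed Integer seed; per-imputation seeds are derived from it.
#' @return An object of class `mi_pooled`; see [tidy.mi_pooled()] and
#'   [glance.mi_pooled()].
#' @examples
#' spec <- scenario_spec("S1", beta_YX = 1, beta_RY = 1, beta_RZ = 1)
#' d <- simulate_scenario(spec, n = 500, seed = 7)
#' fit <- mi_estimate(d, "x", m = 5, seed = 7)
#' tidy(fit)
#' @export
mi_estimate <- function(data, imputation_predictors, m = 10, seed = 1) {
  spec <- dataset_spec(data)
  if (!is.numeric(m) || m < 2) {
    rlang::abort("`m` must be an integer >= 2.", class = "auxbias_spec_error")
  }
  m <- as.integer(m)
  fit <- fit_imputation_model(data, imputation_predictors)
  set.seed(as.integer(seed))
  imp_seeds <- sample.int(2147483646L, m)
  binary_y <- spec$y_type == "binary"
  per_imp <- vapply(seq_len(m), function(j) {
    completed <- draw_and_impute(fit, data, seed = imp_seeds[j])
    if (fit$response == "y") {
      analysis_fit(completed, data$x, binary_y)
    } else {
      analysis_fit(data$y, completed, binary_y)
    }
  }, c(estimate = 0, variance = 0))
  estimates <- per_imp["estimate", ]
  pooled <- rubin_pool(estimates, per_imp["variance", ])
  structure(
    c(pooled, list(
      estimates = estimates,
      imputation_predictors = imputation_predictors,
      analysis_family = if (binary_y) "logistic" else "linear",
      seed = as.integer(seed)
    )),
    class = "mi_pooled"
  )
}

#' @export
print.mi_pooled <- function(x, ...) {
  cat(sprintf(
    "<mi_pooled> m = %d, imputation predictors: %s\n", x$m,
    paste(x$imputation_predictors, collapse = ", ")
  ))
  cat(sprintf("  pooled estimate %.4f (SE %.4f)\n",
              x$pooled_estimate, sqrt(x$pooled_variance)))
  invisible(x)
}

#' Tidy an MI pooled estimate
#'
#' @param x An [mi_estimate()] result.
#' @param ... Unused.
#' @return `tidy()`: a one-row tibble with `term`, `estimate`, `std.error`.
#'   `glance()`: a one-row tibble with `m`, the Rubin variance components
#'   (`within_variance`, `between_variance`, `pooled_variance`) and the
#'   analysis family. The pooled SE carries no small-sample
#'   degrees-of-freedom adjustment.
#' @exportS3Method generics::tidy
tidy.mi_pooled <- function(x, ...) {
  tibble::tibble(
    term = "x",
    estimate = x$pooled_estimate,
    std.error = sqrt(x$pooled_variance)
  )
}

#' @rdname tidy.mi_pooled
#' @exportS3Method generics::glance
glance.mi_pooled <- function(x, ...) {
  tibble::tibble(
    m = x$m,
    within_variance = x$within_variance,
    between_variance = x$between_variance,
    pooled_variance = x$pooled_variance,
    analysis_family = x$analysis_family
  )
}

#' Complete-records estimate of the exposure coefficient
#'
#' Fits the analysis model (regression of `Y` on `X`) to the records with
#' `r_ind = 1` only — the comparator every MI strategy is judged against.
#'
#' @param data A [simulate_scenario()] result.
#' @return A one-row tibble with `estimate`, `std.error` and `n_obs`.
#' @export
cra_estimate <- function(data) {
  spec <- dataset_spec(data)
  obs <- data$r_ind == 1L
  if (sum(obs) < 3) {
    rlang::abort("Fewer than 3 complete records.", class = "auxbias_fit_error")
  }
  res <- analysis_fit(data$y[obs], data$x[obs], spec$y_type == "binary")
  tibble::tibble(
    estimate = res[["estimate"]],
    std.error = sqrt(res[["variance"]]),
    n_obs = sum(obs)
  )
}
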