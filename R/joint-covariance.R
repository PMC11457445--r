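#' Implied joint distribution of (X, Z, U, Y, R)
#'
#' Every scenario is a linear-Gaussian path model, so the joint distribution
#' of the five variables is multivariate normal with moments obtained by
#' structural substitution: each endogenous variable is a linear combination
#' of the exogenous variables and the mutually independent error terms. With
#' `A` the matrix of loadings onto the exogenous basis
#' `(e_X, e_Z, e_U, e_Y, e_R)` and `D` the diagonal of error variances, the
#' covariance is `A D A'`. This constructor is the substrate of the
#' population partial-regression oracle ([partial_regression_coef()]) used to
#' cross-check every closed-form bias expression.
#'
#' All five variables are represented in every scenario; variables absent
#' from a diagram simply carry zero path coefficients, so one code path
#' serves all DAGs.
#'
#' @param spec A [scenario_spec()].
#' @return An object of class `joint_covariance`: a list with `order`
#'   (`c("x", "z", "u", "y", "r")`), `means` (length-5 named vector, including
#'   the derived mean of the latent score `R`), and `cov` (symmetric
#'   positive-semidefinite 5x5 matrix).
#' @examples
#' jc <- build_joint_covariance(
#'   scenario_spec("S1", beta_YX = 1, beta_RY = 1, beta_RZ = 1)
#' )
#' jc$cov
#' @export
build_joint_covariance <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  vars <- c("x", "z", "u", "y", "r")

  # loadings of each variable on the exogenous basis (e_X, e_Z, e_U, e_Y, e_R)
  A <- matrix(0, 5, 5, dimnames = list(vars, c("eX", "eZ", "eU", "eY", "eR")))
  A["x", "eX"] <- 1
  A["z", "eZ"] <- 1
  A["u", "eU"] <- 1
  A["y", ] <- spec$beta_YX * A["x", ] + spec$beta_YU * A["u", ]
  A["y", "eY"] <- 1
  A["r", ] <- spec$beta_RY * A["y", ] + spec$beta_RX * A["x", ] +
    spec$beta_RZ * A["z", ] + spec$beta_RU * A["u", ]
  A["r", "eR"] <- 1

  D <- diag(c(spec$var_X, spec$var_Z, spec$var_U, spec$var_Y, spec$var_R))
  cov <- A %*% D %*% t(A)
  cov <- (cov + t(cov)) / 2
  dimnames(cov) <- list(vars, vars)

  mu_y <- spec$beta_YX * spec$mu_X + spec$beta_YU * spec$mu_U
  mu_r <- spec$beta_RY * mu_y + spec$beta_RX * spec$mu_X +
    spec$beta_RZ * spec$mu_Z + spec$beta_RU * spec$mu_U
  means <- c(x = spec$mu_X, z = spec$mu_Z, u = spec$mu_U, y = mu_y, r = mu_r)

  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    rlang::abort("Implied covariance is not positive semidefinite.",
                 class = "auxbias_numeric_error")
  }

  structure(list(order = vars, means = means, cov = cov),
            class = "joint_covariance")
}

#' @export
print.joint_covariance <- function(x, ...) {
  cat("<joint_covariance> over (", paste(x$order, collapse = ", "), ")\n",
      sep = "")
  cat("means:\n")
  print(round(x$means, 6))
  cat("covariance:\n")
  print(round(x$cov, 6))
  invisible(x)
}

#' Population partial-regression coefficients
#'
#' Returns the coefficients of the population least-squares projection of
#' `target` on `predictors` under the multivariate-normal joint distribution:
#' the inverse of the predictor covariance block times the predictor-target
#' covariance vector. Limiting MI coefficients such as the exposure
#' coefficient from a regression of `Y` on `X` and `R` are exactly such
#' projections, which makes this function the independent oracle for all the
#' closed-form bias expressions.
#'
#' @param jc A [build_joint_covariance()] result.
#' @param target Variable name, one of `jc$order`.
#' @param predictors Character vector of distinct predictor names (intercept
#'   implicit; coefficients do not depend on the means).
#' @return Named numeric vector of coefficients, one per predictor.
#' @examples
#' jc <- build_joint_covariance(
#'   scenario_spec("S1", beta_YX = 1, beta_RY = 1, beta_RZ = 1)
#' )
#' partial_regression_coef(jc, "y", c("x", "r")) # c(2/3, 1/3)
#' @export
partial_regression_coef <- function(jc, target, predictors) {
  stopifnot(inherits(jc, "joint_covariance"))
  nm <- unique(c(target, predictors))
  if (length(nm) != length(predictors) + 1L || !all(nm %in% jc$order)) {
    rlang::abort(
      "`target` and `predictors` must be distinct members of the variable ordering.",
      class = "auxbias_oracle_error"
    )
  }
  S_pp <- jc$cov[predictors, predictors, drop = FALSE]
  s_pt <- jc$cov[predictors, target]
  qr_S <- qr(S_pp)
  if (qr_S$rank < length(predictors)) {
    rlang::abort(
      sprintf("Predictor block {%s} is singular (collinear in this scenario).",
              paste(predictors, collapse = ", ")),
      class = "auxbias_oracle_error"
    )
  }
  coefs <- drop(solve(qr_S, s_pt))
  names(coefs) <- predictors
  coefs
}
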