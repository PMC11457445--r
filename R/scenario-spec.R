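#' Define a missingness scenario
#'
#' A scenario spec fully parameterises one of the causal diagrams studied by
#' the package: a continuous outcome `Y` caused by exposure `X` (and possibly
#' an unmeasured variable `U`), a fully observed candidate auxiliary variable
#' `Z`, and a latent-normal missingness score `R` that determines which values
#' of the incomplete variable are observed. Three diagrams are supported,
#' each with the outcome (`_Y`) or the exposure (`_X`) incomplete:
#'
#' * `"S1"` — missingness caused by the outcome itself
#'   (`R = beta_RY * Y + beta_RZ * Z + e_R`); `Y` incomplete.
#' * `"S2_Y"` / `"S2_X"` — missingness related to the outcome only through an
#'   unmeasured variable `U` (`Y = beta_YX * X + beta_YU * U + e_Y`,
#'   `R = beta_RZ * Z + beta_RU * U + e_R`).
#' * `"S3_Y"` / `"S3_X"` — missingness caused by both outcome and exposure
#'   (`R = beta_RY * Y + beta_RX * X + beta_RZ * Z + e_R`).
#'
#' Path coefficients that are absent from the chosen diagram must be exactly
#' zero; supplying a nonzero value is an error rather than being silently
#' ignored, so a degenerate scenario cannot be run by accident.
#'
#' @param scenario_id One of `"S1"`, `"S2_Y"`, `"S2_X"`, `"S3_Y"`, `"S3_X"`.
#' @param beta_YX Direct effect of `X` on `Y` (the analysis-model estimand).
#' @param beta_YU Direct effect of `U` on `Y` (S2 only).
#' @param beta_RY Direct effect of `Y` on the latent score `R` (S1, S3).
#' @param beta_RX Direct effect of `X` on `R` (S3 only).
#' @param beta_RZ Direct effect of `Z` on `R` (all scenarios).
#' @param beta_RU Direct effect of `U` on `R` (S2 only).
#' @param var_Y,var_X,var_Z,var_U,var_R Strictly positive error variances of
#'   the structural equations (for the exogenous `X`, `Z`, `U` these are the
#'   marginal variances).
#' @param mu_X,mu_Z,mu_U Means of the exogenous variables. Bias quantities are
#'   location-free, so these default to zero; they only move thresholds.
#' @param pi_obs Probability that a value is observed,
#'   `P(R_ind = 1) = P(R <= r)`, in `(0, 1]`.
#' @param y_type,x_type `"continuous"` or `"binary"`. Binary variables are
#'   dichotomised from their latent-normal form after all structural equations
#'   have been evaluated.
#' @param y_prevalence,x_prevalence Target `P(= 1)` for a binary variable.
#'
#' @return An object of class `scenario_spec`: a named list of the validated
#'   parameters plus `incomplete_var` (`"y"` or `"x"`).
#' @examples
#' spec <- scenario_spec("S1", beta_YX = 1, beta_RY = 1, beta_RZ = 1)
#' spec
#' @seealso [build_joint_covariance()], [simulate_scenario()], [bias_summary()]
#' @export
scenario_spec <- function(scenario_id,
                          beta_YX = 0, beta_YU = 0,
                          beta_RY = 0, beta_RX = 0, beta_RZ = 0, beta_RU = 0,
                          var_Y = 1, var_X = 1, var_Z = 1, var_U = 1, var_R = 1,
                          mu_X = 0, mu_Z = 0, mu_U = 0,
                          pi_obs = 0.5,
                          y_type = c("continuous", "binary"),
                          x_type = c("continuous", "binary"),
                          y_prevalence = 0.5, x_prevalence = 0.5) {
  scenario_id <- rlang::arg_match(scenario_id, scenario_ids())
  y_type <- rlang::arg_match(y_type)
  x_type <- rlang::arg_match(x_type)

  num <- function(v) if (is.numeric(v)) as.double(v) else v
  spec <- list(
    scenario_id = scenario_id,
    beta_YX = num(beta_YX), beta_YU = num(beta_YU),
    beta_RY = num(beta_RY), beta_RX = num(beta_RX), beta_RZ = num(beta_RZ),
    beta_RU = num(beta_RU),
    var_Y = num(var_Y), var_X = num(var_X), var_Z = num(var_Z),
    var_U = num(var_U), var_R = num(var_R),
    mu_X = num(mu_X), mu_Z = num(mu_Z), mu_U = num(mu_U),
    pi_obs = num(pi_obs),
    y_type = y_type, x_type = x_type,
    y_prevalence = num(y_prevalence), x_prevalence = num(x_prevalence)
  )
  spec$incomplete_var <- if (endsWith(scenario_id, "_X")) "x" else "y"
  class(spec) <- "scenario_spec"
  validate_scenario_spec(spec)
}

scenario_ids <- function() c("S1", "S2_Y", "S2_X", "S3_Y", "S3_X")

# coefficients that are structurally present in each diagram
active_coefs <- function(scenario_id) {
  switch(scenario_id,
    S1 = c("beta_YX", "beta_RY", "beta_RZ"),
    S2_Y = ,
    S2_X = c("beta_YX", "beta_YU", "beta_RZ", "beta_RU"),
    S3_Y = ,
    S3_X = c("beta_YX", "beta_RY", "beta_RX", "beta_RZ")
  )
}

validate_scenario_spec <- function(spec) {
  num_fields <- c(
    "beta_YX", "beta_YU", "beta_RY", "beta_RX", "beta_RZ", "beta_RU",
    "var_Y", "var_X", "var_Z", "var_U", "var_R",
    "mu_X", "mu_Z", "mu_U", "pi_obs", "y_prevalence", "x_prevalence"
  )
  for (f in num_fields) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      rlang::abort(
        sprintf("`%s` must be a single finite number.", f),
        class = "auxbias_spec_error"
      )
    }
  }
  vars <- c("var_Y", "var_X", "var_Z", "var_U", "var_R")
  bad <- vars[vapply(vars, function(f) spec[[f]] <= 0, logical(1))]
  if (length(bad) > 0) {
    rlang::abort(
      sprintf(
        "Error variances must be strictly positive; offending: %s.",
        paste(bad, collapse = ", ")
      ),
      class = "auxbias_spec_error"
    )
  }
  if (spec$pi_obs <= 0 || spec$pi_obs > 1) {
    rlang::abort("`pi_obs` must lie in (0, 1].", class = "auxbias_spec_error")
  }
  for (f in c("y_prevalence", "x_prevalence")) {
    if (spec[[f]] <= 0 || spec[[f]] >= 1) {
      rlang::abort(
        sprintf("`%s` must lie strictly in (0, 1).", f),
        class = "auxbias_spec_error"
      )
    }
  }
  all_coefs <- c("beta_YX", "beta_YU", "beta_RY", "beta_RX", "beta_RZ", "beta_RU")
  inactive <- setdiff(all_coefs, active_coefs(spec$scenario_id))
  nonzero <- inactive[vapply(inactive, function(f) spec[[f]] != 0, logical(1))]
  if (length(nonzero) > 0) {
    rlang::abort(
      sprintf(
        "Coefficient(s) %s are not part of scenario %s and must be zero.",
        paste(nonzero, collapse = ", "), spec$scenario_id
      ),
      class = "auxbias_spec_error"
    )
  }
  spec
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec %s>  incomplete: %s (%s)\n",
    x$scenario_id, toupper(x$incomplete_var),
    if (x$incomplete_var == "y") x$y_type else x$x_type
  ))
  act <- active_coefs(x$scenario_id)
  cat("  effects:  ",
      paste(sprintf("%s = %g", act, unlist(x[act])), collapse = ", "), "\n")
  cat("  variances:",
      paste(sprintf("%s = %g", c("var_Y", "var_X", "var_Z", "var_U", "var_R"),
                    unlist(x[c("var_Y", "var_X", "var_Z", "var_U", "var_R")])),
            collapse = ", "), "\n")
  cat(sprintf("  P(observed) = %g\n", x$pi_obs))
  invisible(x)
}

#' Structural parameters used to generate data
#'
#' Pure accessor exporting the generating values of a scenario (notably
#' `beta_YX`, the analysis-model estimand) as a one-row tibble, for use by
#' downstream bias computations.
#'
#' @param spec A [scenario_spec()].
#' @return A one-row tibble with the scenario id, all six path coefficients,
#'   the five error variances, the means and `pi_obs`.
#' @export
true_structural_params <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  tibble::as_tibble(spec[c(
    "scenario_id",
    "beta_YX", "beta_YU", "beta_RY", "beta_RX", "beta_RZ", "beta_RU",
    "var_Y", "var_X", "var_Z", "var_U", "var_R",
    "mu_X", "mu_Z", "mu_U", "pi_obs"
  )])
}

#' Read and write scenario specs as JSON
#'
#' A spec serialises to a flat key/value JSON object whose keys are exactly
#' the constructor arguments of [scenario_spec()]. Unknown keys in a file are
#' rejected rather than ignored.
#'
#' @param spec A [scenario_spec()].
#' @param path File path.
#' @return `write_scenario_spec()` returns `spec` invisibly;
#'   `read_scenario_spec()` returns a validated [scenario_spec()].
#' @export
write_scenario_spec <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  fields <- spec[setdiff(names(spec), "incomplete_var")]
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  invisible(spec)
}

#' @rdname write_scenario_spec
#' @export
read_scenario_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(scenario_spec))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    rlang::abort(
      sprintf("Unknown key(s) in scenario config: %s.",
              paste(unknown, collapse = ", ")),
      class = "auxbias_spec_error"
    )
  }
  do.call(scenario_spec, raw)
}
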