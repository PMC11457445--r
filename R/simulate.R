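#' Simulate one dataset from a scenario
#'
#' Draws `n` independent records from the linear-Gaussian path model of a
#' scenario. The exogenous variables and error terms are sampled from their
#' normal distributions, the endogenous `Y` and latent missingness score `R`
#' are built from their structural equations, and the observation threshold
#' is set at the population quantile `r = mu_R + sqrt(V_R) * qnorm(pi_obs)`
#' using the model-implied moments from [build_joint_covariance()], so that
#' `P(R <= r) = pi_obs` exactly in expectation (no per-sample calibration).
#' A record is observed (`r_ind = 1`) when its latent score falls at or
#' below the threshold.
#'
#' When `Y` (or `X`) is declared binary, all structural equations and the
#' missingness model operate on the latent continuous variable and
#' dichotomisation happens last ([dichotomize()]); downstream imputation and
#' analysis see only the binary version. `U` is generated only in the S2
#' scenarios (elsewhere it is structurally absent and the column is zero),
#' is retained for diagnostics, and is never available to imputation.
#'
#' The generator is deterministic given `(spec, n, seed)`.
#'
#' @param spec A [scenario_spec()].
#' @param n Number of records (at least 10).
#' @param seed Integer seed.
#' @return A tibble of class `sim_dataset` with columns `y`, `x`, `z`, `u`,
#'   `r_latent`, `r_ind` and attributes `spec` and `seed`. Values of the
#'   incomplete variable are all present in the tibble (the mask is
#'   `r_ind`); use [mask_unobserved()] or [export_dataset()] for the
#'   observed-data view.
#' @examples
#' d <- simulate_scenario(
#'   scenario_spec("S1", beta_YX = 1, beta_RY = 1, beta_RZ = 1),
#'   n = 1000, seed = 1
#' )
#' mean(d$r_ind)
#' @export
simulate_scenario <- function(spec, n, seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 10) {
    rlang::abort("`n` must be a single integer >= 10.",
                 class = "auxbias_spec_error")
  }
  n <- as.integer(n)
  jc <- build_joint_covariance(spec)

  set.seed(as.integer(seed))
  x_lat <- stats::rnorm(n, spec$mu_X, sqrt(spec$var_X))
  z <- stats::rnorm(n, spec$mu_Z, sqrt(spec$var_Z))
  u <- if (startsWith(spec$scenario_id, "S2")) {
    stats::rnorm(n, spec$mu_U, sqrt(spec$var_U))
  } else {
    numeric(n)
  }
  y_lat <- spec$beta_YX * x_lat + spec$beta_YU * u +
    stats::rnorm(n, 0, sqrt(spec$var_Y))
  r_latent <- spec$beta_RY * y_lat + spec$beta_RX * x_lat +
    spec$beta_RZ * z + spec$beta_RU * u +
    stats::rnorm(n, 0, sqrt(spec$var_R))

  threshold <- jc$means["r"] + sqrt(jc$cov["r", "r"]) * stats::qnorm(spec$pi_obs)
  r_ind <- as.integer(r_latent <= threshold)

  y <- if (spec$y_type == "binary") {
    dichotomize(y_lat, spec$y_prevalence,
                mean = jc$means["y"], sd = sqrt(jc$cov["y", "y"]))
  } else {
    y_lat
  }
  x <- if (spec$x_type == "binary") {
    dichotomize(x_lat, spec$x_prevalence,
                mean = jc$means["x"], sd = sqrt(jc$cov["x", "x"]))
  } else {
    x_lat
  }

  out <- tibble::tibble(y = y, x = x, z = z, u = u,
                        r_latent = r_latent, r_ind = r_ind)
  attr(out, "spec") <- spec
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("sim_dataset", class(out))
  out
}

#' Dichotomise a latent-normal variable at a target prevalence
#'
#' Thresholds at the population `(1 - prevalence)` quantile of the variable's
#' marginal normal distribution (`mean + sd * qnorm(1 - prevalence)`),
#' returning 1 above the threshold — a population quantile, not a sample
#' quantile, so the realised prevalence matches the target only up to
#' binomial sampling error.
#'
#' @param values Numeric vector (latent continuous values).
#' @param prevalence Target `P(= 1)`, strictly in (0, 1).
#' @param mean,sd Population mean and standard deviation of the variable's
#'   marginal normal distribution (model-implied, not estimated from
#'   `values`).
#' @return Integer vector of 0/1.
#' @examples
#' x <- rnorm(1e4)
#' mean(dichotomize(x, 0.2)) # ~ 0.2
#' @export
dichotomize <- function(values, prevalence, mean = 0, sd = 1) {
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
    rlang::abort("`prevalence` must lie strictly in (0, 1).",
                 class = "auxbias_spec_error")
  }
  if (!is.numeric(sd) || sd <= 0) {
    rlang::abort("Degenerate (zero-variance) variable cannot be dichotomised.",
                 class = "auxbias_spec_error")
  }
  as.integer(values > mean + sd * stats::qnorm(1 - prevalence))
}

#' Observed-data view of a simulated dataset
#'
#' Returns the dataset with the incomplete variable set to `NA` wherever
#' `r_ind = 0`, i.e. what an analyst would actually see.
#'
#' @param data A [simulate_scenario()] result.
#' @return A tibble with the same columns, incomplete values masked.
#' @export
mask_unobserved <- function(data) {
  spec <- dataset_spec(data)
  iv <- spec$incomplete_var
  data[[iv]][data$r_ind == 0L] <- NA_real_
  data
}

#' Export a simulated dataset to CSV
#'
#' Writes the observed-data view (incomplete values masked to `NA`) with
#' columns `y`, `x`, `z`, `r_ind`; with `debug = TRUE` the diagnostic columns
#' `u` and `r_latent` are appended.
#'
#' @param data A [simulate_scenario()] result.
#' @param path Output file path.
#' @param debug Include `u` and `r_latent`?
#' @return `path`, invisibly.
#' @export
export_dataset <- function(data, path, debug = FALSE) {
  masked <- mask_unobserved(data)
  cols <- c("y", "x", "z", "r_ind")
  if (debug) cols <- c(cols, "u", "r_latent")
  utils::write.csv(as.data.frame(masked[cols]), path, row.names = FALSE)
  invisible(path)
}

dataset_spec <- function(data) {
  spec <- attr(data, "spec")
  if (is.null(spec)) {
    rlang::abort("`data` must be a dataset produced by simulate_scenario().",
                 class = "auxbias_spec_error")
  }
  spec
}

# Deterministic substream seeds: replicate k of a study seeded with `seed`
# uses seed + k * 100003 (a prime stride), reduced mod 2^31 - 1 to stay a
# valid 32-bit seed.
replicate_seed <- function(seed, k) {
  as.integer((as.double(seed) + as.double(k) * 100003) %% 2147483647)
}
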