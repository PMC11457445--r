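#' Closed-form bias measures over a factorial effect-size grid
#'
#' Evaluates [bias_summary()] over the full factorial of `effect_values` for
#' the scenario's missingness-relevant direct effects, with all error
#' variances fixed at one so the biases read as both absolute and
#' error-variance-relative. For S1 the grid spans
#' `(beta_YX, beta_RY, beta_RZ)`; for S3 with the outcome incomplete it also
#' spans `beta_RX`. The default values `0, 0.25, 0.5, 0.75, 1` correspond
#' on the missingness scale to odds ratios of roughly 1, 1.5, 2.3, 3.5 and
#' 5.3 ([probit_to_odds_ratio()]).
#'
#' @param effect_values Numeric vector of direct effect sizes.
#' @param scenario `"S1"` or `"S3_Y"`.
#' @return A tibble of class `auxbias_grid`: one row per grid cell with the
#'   effect sizes and all [bias_summary()] measures.
#' @examples
#' grid <- run_grid_closed_form(c(0, 0.5, 1), "S1")
#' dplyr::filter(grid, beta_YX == 1, beta_RY == 1, beta_RZ == 1)
#' @export
run_grid_closed_form <- function(effect_values = c(0, 0.25, 0.5, 0.75, 1),
                                 scenario = c("S1", "S3_Y")) {
  scenario <- rlang::arg_match(scenario)
  effects <- if (scenario == "S1") {
    c("beta_YX", "beta_RY", "beta_RZ")
  } else {
    c("beta_YX", "beta_RY", "beta_RX", "beta_RZ")
  }
  grid <- tidyr::expand_grid(!!!rlang::set_names(
    rep(list(effect_values), length(effects)), effects
  ))
  out <- dplyr::bind_cols(
    grid,
    purrr::pmap_dfr(grid, function(...) {
      args <- c(list(scenario_id = scenario), list(...))
      dplyr::select(bias_summary(do.call(scenario_spec, args)), -"scenario_id")
    })
  )
  class(out) <- c("auxbias_grid", class(out))
  attr(out, "scenario") <- scenario
  out
}

# shared Monte-Carlo core: per replicate, simulate, MI without and with the
# auxiliary, and the complete-records fit; failed replicates are counted and
# the study aborts if more than 1% fail
mc_core <- function(spec, n, replicates, m, seed) {
  no_aux <- if (spec$incomplete_var == "y") "x" else "y"
  with_aux <- c(no_aux, "z")
  res <- purrr::map(seq_len(replicates), function(k) {
    s <- replicate_seed(seed, k)
    tryCatch({
      d <- simulate_scenario(spec, n, seed = s)
      tibble::tibble(
        replicate = k,
        est_no_aux = mi_estimate(d, no_aux, m, seed = s + 1L)$pooled_estimate,
        est_with_aux = mi_estimate(d, with_aux, m, seed = s + 2L)$pooled_estimate,
        est_cra = cra_estimate(d)$estimate
      )
    }, auxbias_fit_error = function(e) NULL)
  })
  failed <- sum(vapply(res, is.null, logical(1)))
  if (failed > 0.01 * replicates) {
    rlang::abort(
      sprintf("%d of %d replicates failed to fit (> 1%%); study aborted.",
              failed, replicates),
      class = "auxbias_study_error"
    )
  }
  list(estimates = dplyr::bind_rows(res), n_failed = failed)
}

#' Monte-Carlo bias study for one scenario
#'
#' Runs `replicates` independent simulated datasets through the full MI
#' pipeline twice — imputation model with the analysis variables only, and
#' additionally with the auxiliary `Z` — plus the complete-records fit, and
#' reports the empirical bias of each estimator relative to the generating
#' `beta_YX`, with Monte-Carlo standard errors (SD of replicate estimates /
#' sqrt(replicates)). Where a closed-form limit exists for the scenario it
#' is attached as a list-column for side-by-side reading.
#'
#' @param spec A [scenario_spec()] (continuous variables; for binary
#'   variants see [binary_variant_study()]).
#' @param n Records per replicate.
#' @param replicates Number of Monte-Carlo replicates (>= 50 recommended).
#' @param m Imputations per MI run.
#' @param seed Integer seed; replicate substreams are derived from it.
#' @return A one-row tibble of class `study_result` with columns
#'   `scenario_id`, `n`, `replicates`, `m`, `seed`, `mi_bias_no_aux`,
#'   `mi_bias_with_aux`, `additional_bias`, `cra_bias`, the three
#'   `mc_se_*` columns, `n_failed` and `closed_form_reference`. The
#'   replicate-level estimates are attached as attribute `"estimates"`.
#' @export
run_mc_study <- function(spec, n = 5000, replicates = 500, m = 10, seed = 1) {
  stopifnot(inherits(spec, "scenario_spec"))
  core <- mc_core(spec, n, replicates, m, seed)
  est <- core$estimates
  beta_true <- spec$beta_YX
  mc_se <- function(v) stats::sd(v) / sqrt(length(v))
  reference <- tryCatch(bias_summary(spec), error = function(e) NULL)
  out <- tibble::tibble(
    scenario_id = spec$scenario_id,
    n = n, replicates = replicates, m = m, seed = as.integer(seed),
    mi_bias_no_aux = mean(est$est_no_aux) - beta_true,
    mi_bias_with_aux = mean(est$est_with_aux) - beta_true,
    additional_bias = mean(est$est_with_aux) - mean(est$est_no_aux),
    cra_bias = mean(est$est_cra) - beta_true,
    mc_se_no_aux = mc_se(est$est_no_aux),
    mc_se_with_aux = mc_se(est$est_with_aux),
    mc_se_cra = mc_se(est$est_cra),
    n_failed = core$n_failed,
    closed_form_reference = list(reference)
  )
  class(out) <- c("study_result", class(out))
  attr(out, "estimates") <- est
  out
}

#' Convergence of the MI estimator to its closed-form limit
#'
#' As the observed proportion `pi_obs` descends towards zero, the mean MI
#' estimate (with and without the auxiliary in the imputation model)
#' approaches the closed-form limiting coefficients. This runs a small
#' Monte-Carlo study at each `pi_obs` in a decreasing sequence and tabulates
#' the gap to the limit.
#'
#' @param spec A [scenario_spec()] with a closed-form limit (S1 or S3_Y).
#' @param pi_obs_sequence Decreasing vector of observed proportions; the
#'   study requires at least 500 expected observed records at the smallest.
#' @param n Records per replicate.
#' @param replicates Replicates per `pi_obs`.
#' @param m Imputations per MI run.
#' @param seed Integer seed.
#' @return A tibble of class `auxbias_limits`: one row per `pi_obs` with the
#'   mean MI estimates, their Monte-Carlo standard errors, the closed-form
#'   limits and the gaps to them, plus the exact finite-missingness
#'   expectations from [expected_mi_coef()] (which the estimates should match
#'   within Monte-Carlo error at every `pi_obs`, not only in the limit).
#' @export
limiting_case_check <- function(spec, pi_obs_sequence = c(1, 0.5, 0.25, 0.1, 0.02),
                                n = 20000, replicates = 50, m = 10, seed = 1) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!spec$scenario_id %in% c("S1", "S3_Y")) {
    rlang::abort("A closed-form limit exists only for scenarios S1 and S3_Y.",
                 class = "auxbias_spec_error")
  }
  if (is.unsorted(rev(pi_obs_sequence), strictly = TRUE)) {
    rlang::abort("`pi_obs_sequence` must be strictly decreasing.",
                 class = "auxbias_spec_error")
  }
  if (n * min(pi_obs_sequence) < 500) {
    rlang::abort(
      sprintf(
        "Expected observed count %.0f at the smallest pi_obs is below 500; increase `n`.",
        n * min(pi_obs_sequence)
      ),
      class = "auxbias_spec_error"
    )
  }
  ref <- bias_summary(spec)
  no_aux <- "x"
  rows <- purrr::imap(pi_obs_sequence, function(p, i) {
    spec_p <- spec
    spec_p$pi_obs <- p
    spec_p <- validate_scenario_spec(spec_p)
    core <- mc_core(spec_p, n, replicates, m,
                    seed = replicate_seed(seed, i * 1000L))
    est <- core$estimates
    mc_se <- function(v) stats::sd(v) / sqrt(length(v))
    tibble::tibble(
      pi_obs = p,
      est_no_aux = mean(est$est_no_aux),
      mc_se_no_aux = mc_se(est$est_no_aux),
      est_with_aux = mean(est$est_with_aux),
      mc_se_with_aux = mc_se(est$est_with_aux),
      limit_no_aux = ref$coef_limit_no_aux,
      limit_with_aux = ref$coef_limit_with_aux,
      gap_no_aux = abs(mean(est$est_no_aux) - ref$coef_limit_no_aux),
      gap_with_aux = abs(mean(est$est_with_aux) - ref$coef_limit_with_aux),
      expected_no_aux = expected_mi_coef(spec_p),
      expected_with_aux = expected_mi_coef(spec_p, include_aux = TRUE)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$beta_true <- spec$beta_YX
  class(out) <- c("auxbias_limits", class(out))
  out
}

#' Monte-Carlo bias study with a dichotomised outcome or exposure
#'
#' As [run_mc_study()], but for scenarios in which `Y` or `X` is binary, so
#' the imputation (and, for binary `Y`, the analysis) model is logistic and
#' the bias target is no longer the latent-scale `beta_YX`. The reference
#' coefficient is therefore computed at run time as the analysis-model
#' coefficient on one large fully observed dataset (`ref_n` records)
#' generated from the same spec — for binary `Y` this is the large-sample
#' log-odds coefficient of `X`.
#'
#' @inheritParams run_mc_study
#' @param ref_n Size of the complete reference dataset.
#' @return As [run_mc_study()], plus columns `beta_reference` (the
#'   large-sample complete-data coefficient) and `var_x_observed` (sample
#'   variance of `X`, a diagnostic for dichotomised exposures).
#' @export
binary_variant_study <- function(spec, n = 5000, replicates = 500, m = 10,
                                 seed = 1, ref_n = 200000) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$y_type != "binary" && spec$x_type != "binary") {
    rlang::abort("`spec` must declare a binary y_type or x_type.",
                 class = "auxbias_spec_error")
  }
  ref_spec <- spec
  ref_spec$pi_obs <- 1
  ref_spec <- validate_scenario_spec(ref_spec)
  ref_data <- simulate_scenario(ref_spec, ref_n,
                                seed = replicate_seed(seed, 999983L))
  beta_ref <- analysis_fit(ref_data$y, ref_data$x,
                           spec$y_type == "binary")[["estimate"]]

  core <- mc_core(spec, n, replicates, m, seed)
  est <- core$estimates
  mc_se <- function(v) stats::sd(v) / sqrt(length(v))
  out <- tibble::tibble(
    scenario_id = spec$scenario_id,
    n = n, replicates = replicates, m = m, seed = as.integer(seed),
    beta_reference = beta_ref,
    mi_bias_no_aux = mean(est$est_no_aux) - beta_ref,
    mi_bias_with_aux = mean(est$est_with_aux) - beta_ref,
    additional_bias = mean(est$est_with_aux) - mean(est$est_no_aux),
    cra_bias = mean(est$est_cra) - beta_ref,
    mc_se_no_aux = mc_se(est$est_no_aux),
    mc_se_with_aux = mc_se(est$est_with_aux),
    mc_se_cra = mc_se(est$est_cra),
    n_failed = core$n_failed,
    var_x_observed = stats::var(ref_data$x),
    closed_form_reference = list(NULL)
  )
  class(out) <- c("study_result", class(out))
  attr(out, "estimates") <- est
  out
}
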