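# Random valid scenario specs for oracle-equivalence sweeps. Coefficients
# span both signs; error variances stay away from zero so partial-regression
# systems are well conditioned.
random_spec <- function(scenario_id) {
  coef <- function() stats::runif(1, -1.5, 1.5)
  v <- function() stats::runif(1, 0.3, 2.5)
  args <- list(
    scenario_id = scenario_id,
    var_Y = v(), var_X = v(), var_Z = v(), var_U = v(), var_R = v(),
    pi_obs = stats::runif(1, 0.05, 0.95)
  )
  for (b in auxbias:::active_coefs(scenario_id)) args[[b]] <- coef()
  do.call(scenario_spec, args)
}

unit_s1_spec <- function(...) {
  scenario_spec("S1", beta_YX = 1, beta_RY = 1, beta_RZ = 1, ...)
}

# MCAR within the S1 diagram: no paths into R at all
mcar_spec <- function(beta_YX = 1, ...) {
  scenario_spec("S1", beta_YX = beta_YX, ...)
}

# relative comparison with an absolute floor: for coefficients that are
# themselves ~0 the ratio of roundoff to value is meaningless, so scale by
# at least 1e-3 (making the check an absolute 1e-13 there)
expect_rel_equal <- function(actual, expected, rel_tol = 1e-10) {
  scale <- max(abs(expected), 1e-3)
  expect_lt(abs(actual - expected) / scale, rel_tol)
}
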