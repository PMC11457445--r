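test_that("S1 limiting coefficients match hand-derived unit-parameter values", {
  b <- bias_s1_outcome(unit_s1_spec())
  expect_equal(b$coef_limit_no_aux, 2 / 3)
  expect_equal(b$coef_limit_with_aux, 1 / 2)
  expect_equal(b$max_bias, -1 / 3)
  expect_equal(b$max_additional_bias, -1 / 6)
  expect_equal(b$max_total_bias, -1 / 2)
  expect_equal(b$amplification_factor, 1.5)
  expect_equal(b$max_relative_additional_bias, -100 / 6)
})

test_that("S1 degenerate parameter values sever the bias pathways", {
  b0 <- bias_s1_outcome(scenario_spec("S1", beta_RY = 1, beta_RZ = 1))
  expect_equal(b0$max_bias, 0)
  expect_equal(b0$max_additional_bias, 0)
  expect_true(is.na(b0$max_relative_additional_bias)) # undefined, not NaN

  bz <- bias_s1_outcome(scenario_spec("S1", beta_YX = 1, beta_RY = 1))
  expect_equal(bz$max_additional_bias, 0)
  expect_equal(bz$amplification_factor, 1)
})

test_that("S1 bias is towards zero with the documented ordering", {
  set.seed(11)
  for (i in 1:50) {
    spec <- random_spec("S1")
    if (any(c(spec$beta_YX, spec$beta_RY, spec$beta_RZ) == 0)) next
    b <- bias_s1_outcome(spec)
    expect_lt(abs(b$coef_limit_with_aux), abs(b$coef_limit_no_aux))
    expect_lt(abs(b$coef_limit_no_aux), abs(b$beta_true))
    # total bias decomposes exactly
    expect_identical(b$max_total_bias, b$max_bias + b$max_additional_bias)
    expect_gt(b$amplification_factor, 1)
  }
})

test_that("every closed form agrees with the partial-regression oracle", {
  set.seed(202)
  n_sweep <- 300
  for (i in seq_len(n_sweep)) {
    s1 <- random_spec("S1")
    jc <- build_joint_covariance(s1)
    b <- bias_s1_outcome(s1)
    expect_rel_equal(b$coef_limit_no_aux,
                     partial_regression_coef(jc, "y", c("x", "r"))[["x"]])
    expect_rel_equal(b$coef_limit_with_aux,
                     partial_regression_coef(jc, "y", c("x", "z", "r"))[["x"]])

    s2 <- random_spec("S2_X")
    jc2 <- build_joint_covariance(s2)
    b2 <- imputation_coef_bias_s2(s2)
    expect_rel_equal(b2$beta_true,
                     partial_regression_coef(jc2, "x", "y")[["y"]])
    expect_rel_equal(b2$coef_limit_no_aux,
                     partial_regression_coef(jc2, "x", c("y", "r"))[["y"]])
    expect_rel_equal(b2$coef_limit_with_aux,
                     partial_regression_coef(jc2, "x", c("y", "z", "r"))[["y"]])

    s3 <- random_spec("S3_Y")
    jc3 <- build_joint_covariance(s3)
    b3 <- bias_s3_outcome(s3)
    expect_rel_equal(b3$coef_limit_no_aux,
                     partial_regression_coef(jc3, "y", c("x", "r"))[["x"]])
    expect_rel_equal(b3$coef_limit_with_aux,
                     partial_regression_coef(jc3, "y", c("x", "z", "r"))[["x"]])

    s3x <- random_spec("S3_X")
    jc3x <- build_joint_covariance(s3x)
    oracle_diff <- partial_regression_coef(jc3x, "x", c("y", "z", "r"))[["y"]] -
      partial_regression_coef(jc3x, "x", c("y", "r"))[["y"]]
    expect_rel_equal(imputation_coef_additional_bias_s3(s3x), oracle_diff,
                     rel_tol = 1e-9)
  }
})

test_that("negating the exposure effect flips the biases but not the ratios", {
  set.seed(33)
  for (i in 1:25) {
    spec <- random_spec("S1")
    flipped <- spec
    flipped$beta_YX <- -spec$beta_YX
    a <- bias_s1_outcome(spec)
    b <- bias_s1_outcome(auxbias:::validate_scenario_spec(flipped))
    expect_equal(b$max_bias, -a$max_bias)
    expect_equal(b$max_additional_bias, -a$max_additional_bias)
    expect_equal(b$max_total_bias, -a$max_total_bias)
    expect_equal(b$amplification_factor, a$amplification_factor)
    if (spec$beta_YX != 0) {
      expect_equal(b$max_relative_additional_bias, a$max_relative_additional_bias)
    }
  }
})

test_that("S3 with no exposure-to-missingness edge reduces to S1", {
  s3 <- scenario_spec("S3_Y", beta_YX = 0.75, beta_RY = 0.5, beta_RZ = 0.25,
                      var_Y = 1.4, var_Z = 0.9, var_R = 1.1)
  s1 <- scenario_spec("S1", beta_YX = 0.75, beta_RY = 0.5, beta_RZ = 0.25,
                      var_Y = 1.4, var_Z = 0.9, var_R = 1.1)
  expect_equal(
    dplyr::select(bias_s3_outcome(s3), -"scenario_id"),
    dplyr::select(bias_s1_outcome(s1), -"scenario_id")
  )
})

test_that("S3 additional bias always amplifies in the bias direction", {
  b <- bias_s3_outcome(scenario_spec("S3_Y", beta_YX = 1, beta_RY = 1,
                                     beta_RX = 1, beta_RZ = 1))
  expect_equal(b$max_bias, -2 / 3)
  # the ratio of additional to base bias is the amplification factor exactly
  set.seed(44)
  for (i in 1:25) {
    spec <- random_spec("S3_Y")
    bb <- bias_s3_outcome(spec)
    if (bb$max_bias == 0) next
    expect_rel_equal(1 + bb$max_additional_bias / bb$max_bias,
                     bb$amplification_factor)
    expect_gte(sign(bb$max_additional_bias) * sign(bb$max_bias), 0)
  }
  # opposite sign mix can push the bias away from zero
  away <- bias_s3_outcome(scenario_spec("S3_Y", beta_YX = 1, beta_RY = -0.25,
                                        beta_RX = 1, beta_RZ = 1))
  expect_gt(abs(away$coef_limit_no_aux), abs(away$beta_true))
})

test_that("S2 imputation-coefficient limits match the printed fractions", {
  spec <- scenario_spec("S2_X", beta_YX = 1, beta_YU = 1, beta_RU = 1,
                        beta_RZ = 1)
  b <- imputation_coef_bias_s2(spec)
  expect_equal(b$beta_true, 1 / 3)
  expect_equal(b$coef_limit_no_aux, 3 / 8)
  expect_equal(b$coef_limit_with_aux, 2 / 5)
  # bias away from zero, made worse by the auxiliary
  expect_gt(abs(b$coef_limit_with_aux), abs(b$coef_limit_no_aux))
  expect_gt(abs(b$coef_limit_no_aux), abs(b$beta_true))

  # severed MNAR pathway: no bias either way
  for (cut in list(c(beta_YU = 0), c(beta_RU = 0))) {
    args <- list(scenario_id = "S2_X", beta_YX = 1, beta_YU = 1,
                 beta_RU = 1, beta_RZ = 1)
    args[names(cut)] <- cut
    b0 <- imputation_coef_bias_s2(do.call(scenario_spec, args))
    expect_equal(b0$coef_limit_no_aux, b0$beta_true)
    expect_equal(b0$coef_limit_with_aux, b0$beta_true)
  }
  # no auxiliary path: the two limits coincide
  bz <- imputation_coef_bias_s2(scenario_spec("S2_X", beta_YX = 1,
                                              beta_YU = 1, beta_RU = 1))
  expect_equal(bz$coef_limit_no_aux, bz$coef_limit_with_aux)
})

test_that("the S3 exposure-side additional bias vanishes when a pathway is cut", {
  base <- list(scenario_id = "S3_X", beta_YX = 0.8, beta_RY = 0.6,
               beta_RX = 0.9, beta_RZ = 0.7)
  no_z <- base; no_z$beta_RZ <- 0
  expect_equal(imputation_coef_additional_bias_s3(do.call(scenario_spec, no_z)), 0)
  no_x <- base; no_x$beta_RX <- 0
  expect_equal(imputation_coef_additional_bias_s3(do.call(scenario_spec, no_x)), 0)
})

test_that("logistic/probit conversions reproduce the published rounding", {
  expect_equal(round(logistic_to_probit(-0.39), 2), -0.23)
  expect_equal(round(logistic_to_probit(0.44), 2), 0.26)
  expect_equal(round(probit_to_odds_ratio(0.50), 1), 2.3)
  expect_equal(round(probit_to_odds_ratio(0.75), 1), 3.5)
  expect_equal(logistic_to_probit(0), 0)
  expect_equal(probit_to_odds_ratio(0), 1)
})

test_that("the applied amplification estimator matches its rearranged form", {
  amp <- amplification_from_observed(-0.23, 0.18, 0.26, 0.25)
  expect_equal(round(amp, 4), 1.0098)
  expect_equal(round(100 * (amp - 1)), 1)
  expect_equal(amplification_from_observed(0, 0.18, 0.26, 0.25), 1)

  set.seed(55)
  for (i in 1:3) {
    brz <- stats::runif(1, -0.5, 0.5)
    vz <- stats::runif(1, 0.1, 0.4)
    p <- stats::runif(1, -0.5, 0.5)
    vx <- stats::runif(1, 0.1, 0.4)
    a <- brz^2 * vz
    c2 <- p^2 * vx
    rearranged <- 1 + 1 / (1 / a - 1 - c2 / a)
    expect_equal(amplification_from_observed(brz, vz, p, vx), rearranged)
  }
  expect_error(amplification_from_observed(1.5, 1, 0.5, 1),
               class = "auxbias_numeric_error")
})

test_that("bias_summary dispatches by scenario and guards S3_X", {
  expect_identical(bias_summary(unit_s1_spec())$scenario_id, "S1")
  s2y <- scenario_spec("S2_Y", beta_YX = 1, beta_YU = 1, beta_RU = 1,
                       beta_RZ = 1)
  b <- bias_summary(s2y) # unbiased by construction
  expect_equal(b$max_bias, 0)
  expect_equal(b$max_total_bias, 0)
  expect_error(
    bias_summary(scenario_spec("S3_X", beta_YX = 1, beta_RY = 1,
                               beta_RX = 1, beta_RZ = 1)),
    class = "auxbias_spec_error"
  )
})
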