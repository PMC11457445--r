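---
title: "Bias amplification by missingness-only auxiliary variables: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bias amplification by missingness-only auxiliary variables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auxbias)
```

## The problem

Multiple imputation (MI) is unbiased under MAR with a correctly specified,
analysis-compatible imputation model. Under MNAR it is biased, and the
standard mitigation is to enrich the imputation model with auxiliary
variables. This package studies the failure mode of that advice: an
auxiliary variable `Z` that causes missingness but is independent of the
partially observed variable does not carry information about the missing
values — conditioning on it only sharpens the selection effect, and the
MNAR bias grows. `auxbias` quantifies that growth exactly, and verifies the
algebra by simulation.

## Model and assumptions

Everything is built on linear-Gaussian structural equations over
`(X, Z, U, Y, R)`: exogenous `X`, `Z`, `U` are normal; `Y` is a linear
combination of its causes plus normal error; the *latent missingness score*
`R` is a linear combination of its causes plus normal error; a value is
observed when `R ≤ r`, with the threshold set so that `P(observed) = π₁`.
Assumptions inherited from this construction: linearity (no interactions or
non-linear terms), mutually uncorrelated errors, no measurement error, and
correctly specified analysis and imputation models (both ordinary
least-squares / maximum-likelihood regressions). The substantive model is
always the regression of `Y` on `X`; `Z` is never in the analysis model
because it is not a confounder.

Three diagrams are parameterised by `scenario_spec()`; coefficients outside
a diagram are forced to zero at construction so a degenerate scenario cannot
be produced by a typo. All five variables are represented in every scenario
(absent ones with zero paths), so a single covariance constructor
(`build_joint_covariance()`) serves every diagram and can be checked
uniformly.

The means `mu_X`, `mu_Z`, `mu_U` default to zero. Every bias quantity is
location-free, so means only move the observation and dichotomisation
thresholds; they are retained (including the derived mean of `R`) because
the generator needs them.

## The two routes to every number

Each limiting bias expression is implemented twice, independently:

1. **Closed form** (`bias_s1_outcome()`, `bias_s3_outcome()`,
   `imputation_coef_bias_s2()`, `imputation_coef_additional_bias_s3()`):
   the published algebraic expressions in the direct effects and error
   variances.
2. **Population oracle** (`partial_regression_coef()`): the same quantities
   as projections `Σ_pp^{-1} σ_pt` under the implied joint covariance.

The test suite sweeps hundreds of random valid parameterisations per
scenario and requires agreement to 1e-10 relative error (with an absolute
floor of 1e-13 where a coefficient is itself numerically zero, since a pure
ratio test is meaningless against roundoff there).

Two expressions contain a removable 0/0 at `beta_YX = 0` (a `beta_RX /
beta_YX` term whose numerator is elsewhere multiplied by `beta_YX`); they
are evaluated in expanded form so the zero-exposure corner of the factorial
grids evaluates cleanly, and the sweep confirms equivalence everywhere else.

For the exposure-incomplete S2 scenario the reverse-regression coefficient
`beta_XY` is derived from the joint covariance rather than requested from
the user: it is not a free parameter, and asking for it would invite
inconsistent inputs.

Reported conventions: relative additional bias is a percentage of the true
coefficient and is `NA` (an explicit sentinel, not a propagated `NaN`) when
the true coefficient is zero. The amplification factor uses the closed-form
ratio where one exists (S1/S3, defined even when the base bias vanishes);
for S2 it is the ratio of the two inflation-induced biases, set to 1 when
the MNAR pathway is severed and there is no bias to amplify. Conversions in
the applied estimator mirror printed precision (2 dp for coefficients, 1 dp
for odds ratios) only at the display layer; full precision is kept
internally.

## Finite missingness: what the limits do and do not say

The closed forms are *limits* as the missing fraction tends to one: they
condition on `R = r`. At any finite `π₁` the observed records satisfy
`R ≤ r`, a truncation event, and the truncated score retains part of its
variance — about 11% at `π₁ = 0.02`, shrinking only like
`1 / (2 log(1/π₁))`. The practical consequence: even at 98% missingness the
MI estimator sits visibly short of its limit (0.714 rather than 2/3 in the
unit-parameter S1 scenario, 0.600 rather than 1/2 with the auxiliary).

`expected_mi_coef()` closes this gap analytically. One-sided truncation of
`R` shifts every group mean by `a_V (E[R|g] − μ_R)` and shrinks every
covariance by `a_V a_W (Var R − Var(R|g))` with `a_V = Cov(V, R)/Var R`;
the imputation fit converges to the observed-group projection; substituting
it into the missing group and recombining the groups by the law of total
covariance gives the exact large-sample completed-data slope at any `π₁`.
The simulation studies are verified against *this* quantity at every
missingness level (4 Monte-Carlo SEs), while the approach to the asymptotic
limit is asserted as a monotone-descent property. As a by-product the
machinery reproduces, exactly and at every `π₁`, the counter-intuitive S2
result: when missingness is linked to a continuous outcome only through an
unmeasured `U`, both MI and complete-records estimators are unbiased.

```{r finite-pi}
spec <- scenario_spec("S1", beta_YX = 1, beta_RY = 1, beta_RZ = 1,
                      pi_obs = 0.02)
c(limit = bias_summary(spec)$coef_limit_no_aux,
  at_2pct_observed = expected_mi_coef(spec))
```

## The data generator

`simulate_scenario()` draws the exogenous variables and errors, evaluates
the structural equations, and thresholds `R` at the *population* quantile
`μ_R + sqrt(V_R) qnorm(π₁)` — `π₁` is a population probability, so no
per-sample recalibration is done and the realised observed fraction varies
binomially. Design choices worth knowing:

* **Binary variables are latent-first.** When `Y` or `X` is declared
  binary, all structural equations and the missingness model run on the
  latent continuous variable; `dichotomize()` cuts at the model-implied
  population quantile last, and only the binary version is visible
  downstream. This is the latent-normal justification for why the
  continuous-variable algebra approximately carries over (a binary `X` with
  prevalence 0.5 then has mean 0.5 and variance 0.25 rather than the unit
  variance of its continuous counterpart, which is why exposure-side
  results differ between the two).
* **`U` is embargoed.** It is generated (only in S2, where it has edges),
  kept for diagnostics, and rejected as an imputation predictor by
  validation — it plays the "unmeasured" role structurally.
* **Determinism.** A dataset is a pure function of `(spec, n, seed)`.
  Studies derive replicate substreams as `seed + k·100003 (mod 2³¹−1)`, and
  `mi_estimate()` derives per-imputation seeds from its own seed, so every
  table in the package is exactly reproducible from one integer.

What the generator does *not* emulate: non-normal errors, interactions and
non-linearities, multiple simultaneously incomplete variables, measurement
error, and confounding structures beyond the three diagrams. Green tests
therefore certify the algebra and the estimator implementations under the
stated models, not robustness of MI advice in arbitrary real data — though
the qualitative message (missingness-only auxiliaries cannot help and can
hurt) is a DAG-level argument that does not depend on distributional form.

## The MI engine

`mi_estimate()` is proper Bayesian-style imputation with Rubin pooling:

* Linear family: draw `σ*² = σ̂² ν / χ²_ν` (ν = residual df), then
  `β* ~ N(β̂, (σ*²/σ̂²) V_β)`, then impute as linear predictor plus
  `N(0, σ*²)` noise. The exact draw scheme is a design choice (the
  requirement is only "perturb, then draw"); this is the standard
  normal-linear posterior draw, and both the perturbation and the noise can
  be switched off as test hooks.
* Logistic family (binary incomplete variable): `β* ~ N(β̂, V_β)` from the
  asymptotic approximation to the posterior, then Bernoulli draws. Exact
  posterior sampling is out of scope; perfect separation is a reported
  error, not a silent fit.
* One incomplete variable means one conditional draw *is* a valid joint
  draw, so there are no chained-equations iterations.
* Pooling: mean of per-imputation estimates; variance `W + (1 + 1/m) B`.
  The pooled SE is reported without a small-sample degrees-of-freedom
  adjustment — the studies here target bias, not interval length, and the
  MCAR coverage check passes with the normal quantile at the study sizes
  used.
* Defaults: `m = 10` for grid studies (bias is the target; extra
  imputations buy variance reduction that the replicate count already
  provides). The engine accepts any `m ≥ 2`, e.g. 100 for stable applied
  estimates.
* Per-completed-dataset analysis variance is the conventional OLS (or
  observed-information logistic) estimator.

Internally all fits go through thin QR/`glm.fit` wrappers rather than the
`lm()`/`glm()` formula interface: a study fits tens of thousands of small
regressions, and the formula machinery would dominate runtime. The formula
interface is used on the other side of the comparison in the unit tests, as
an independent route.

## Study runner and numerical policy

* Factorial grids use effects `0, 0.25, 0.5, 0.75, 1` with unit error
  variances; box-plot style marginalisation is reproduced as grouped
  summaries/`autoplot()` boxplots rather than bespoke graphics.
* Tolerance policy: algebraic checks at 1e-10 relative (floor above);
  stochastic checks at 4 Monte-Carlo standard errors
  (SD of replicate estimates / √replicates). A study aborts if more than 1%
  of replicates fail (e.g. logistic separation), and counts the failures.
* Binary-variant studies need a bias target on the analysis scale (the
  latent `beta_YX` is not the log-odds coefficient); the reference is the
  analysis coefficient computed at run time on one large (default 200k)
  fully observed dataset from the same spec. That keeps the target exact in
  the only sense available, at the cost of a small, quantified Monte-Carlo
  error in the reference itself.
* Default study sizes in the test suite: grids are exact (no simulation);
  Monte-Carlo checks use n of 400–5000 with 30–500 replicates and m of
  4–10, chosen so that each Monte-Carlo SE is at most ~0.01 on
  unit-variance scales and the whole suite stays in the low minutes on a
  single CPU. The two headline simulation checks (S2 unbiasedness at 500
  replicates of n = 5000; limiting-case behaviour at n = 100000, 100
  replicates) run at full size.

## Applied estimator

`amplification_from_observed()` is the S1 amplification factor rewritten
for quantities estimable from data, under the harmless normalisation
`Var(R) = 1, E(R) = 0`: `1 + β²_RZ σ²_Z / (1 − β²_RZ σ²_Z − (β_RY β_YX)²
σ²_X)`. Its two squared terms are the squared correlations of the auxiliary
and the exposure with missingness; the coefficients come from a logistic
missingness regression times the standard 0.6 logit→probit conversion. A
non-positive denominator means the plugged-in correlations are inconsistent
with a unit-variance latent score, and is an error with that explanation.
The 0.6 rule and the odds-ratio display `exp(coef/0.6)` are approximations;
the package rounds them only for display.

## Known limitations

Single incomplete variable; three fixed diagrams (no user-defined DAGs);
Gaussian errors; linear/logistic families only; no predictive mean
matching; no pattern-mixture/δ-type sensitivity analyses; no delta-method
uncertainty for the applied amplification estimator (its inputs are treated
as known). These are scope boundaries, not oversights: each would change
the estimand or the algebra rather than refine it.
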