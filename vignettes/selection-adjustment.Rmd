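---
title: "Adjusting regression and Mendelian randomization for MNAR selection with instruments for selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjusting regression and Mendelian randomization for MNAR selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnariv)
```

## The problem

Epidemiologic and Mendelian randomization (MR) analyses routinely lose
participants: outcomes are unreported, clinic visits are skipped, exposures
are unmeasured. Standard corrections — complete-case analysis (CCA) and
inverse probability weighting (IPW) — are valid only when data are missing
at random (MAR), i.e. when missingness is fully explained by observed
variables. When selection depends on the partially observed variable itself
(missing not at random, MNAR), both are biased, and no amount of weighting
on observed covariates can fix it.

The estimators in this package use an *instrument for selection*: a fully
observed variable Z that (i) is associated with selection given the
covariates and (ii) is independent of the partially observed variable given
the covariates. Z is an external lever on the selection process; these two
assumptions make MNAR models identifiable. Assumption (i) is testable,
assumption (ii) is not — it plays the role of an exclusion restriction and
its violation can bias the adjusted estimators badly (the `ZY_effect`
simulation scenario reproduces exactly this failure mode).

## The two estimators

### Heckman's sample selection model

The outcome follows a linear model \(Y = X'\beta + \epsilon_1\) and
selection follows a latent-threshold (probit) model
\(R = 1\{\tilde X'\gamma + \epsilon_2 > 0\}\), where \(\tilde X\) contains
Z and possibly the covariates, and
\((\epsilon_1, \epsilon_2)\) are jointly normal with covariance
\(\sigma_{12}\) and \(\mathrm{Var}(\epsilon_2) = \sigma_2^2\). Among
selected individuals,

\[
E(Y \mid X, R = 1) = X'\beta + \frac{\sigma_{12}}{\sigma_2}\,\lambda,
\qquad
\lambda = \frac{\phi(\Lambda)}{1 - \Phi(\Lambda)},
\]

with \(\Lambda = -\tilde X'\gamma/\sigma_2\); \(\lambda\) is the inverse
Mills ratio. `heckman_two_step()` estimates \(\gamma\) by probit regression,
then regresses the observed outcomes on \([X, \hat\lambda]\); the
coefficient on \(\hat\lambda\) estimates \(\sigma_{12}/\sigma_2\).
`heckman_ml()` maximizes the joint bivariate-normal likelihood instead, and
`heckman_binary_ml()` fits the bivariate-probit analogue for a binary
outcome.

Two conventions matter and are fixed once:

* \(\sigma_2\) is not identified by a binary selection indicator, so it is
  set to 1 (the standard probit normalization). The Mills ratio only
  depends on \(\gamma/\sigma_2\), so nothing is lost.
* With \(\sigma_2 = 1\), \(\lambda(-\tilde X'\gamma)\) equals
  \(\phi(\tilde X'\gamma)/\Phi(\tilde X'\gamma)\). The latter form is used
  internally: both the numerator and the log-CDF are evaluated on the log
  scale, so the ratio neither overflows nor degrades to NaN over at least
  \(|\Lambda| \le 40\).

Two-step standard errors use the full Heckman correction: the stage-two
residuals are heteroskedastic
(\(\mathrm{Var} = \sigma_1^2(1 - \rho^2\delta_i)\) with
\(\delta_i = \lambda_i(\lambda_i + \tilde X_i'\gamma)\)), and the
first-stage uncertainty in \(\hat\gamma\) propagates through
\(\hat\lambda\). A plain-OLS mode (`se = "ols"`) exists for diagnostics
only.

### The homogeneous-selection-bias (TTW) estimator

Tchetgen Tchetgen and Wirth's estimator replaces the joint-normality
assumption with a *homogeneous selection bias* assumption: the mean
contrast between selected and non-selected individuals,
\(\delta(X, Z) = E(Y|X,Z,R{=}1) - E(Y|X,Z,R{=}0)\), depends on the
covariates but not on the instrument, \(\delta(X,Z) = \delta(X)\). Then

\[
E(Y \mid X, Z, R = 1) = X'\beta + \delta(X)\,(1 - \pi(X, Z)),
\]

with \(\pi(X,Z) = P(R{=}1|X,Z)\) the selection propensity. With parametric
choices \(\delta(X) = X'\eta\) and a logistic \(\pi\), the joint likelihood
of \((R, Y)\) is maximized by `ttw_fit()`.

`mode = "partial"` (the default, and the configuration used throughout the
simulations) first fits the logistic propensity, then maximizes the outcome
likelihood with \(\pi\) held fixed. A point worth documenting: with \(\pi\)
fixed, the observed-data mean is *linear* in \((\beta, \eta)\) on the link
scale — the stage-two problem is exact least squares on the augmented
design \([X, (1-\hat\pi)X]\) for the linear family, and an ordinary GLM for
the logistic/Poisson families. The package therefore solves it in closed
form rather than iterating; the reported standard errors (inverse negative
Hessian of the stage-two objective) coincide with the classical information
matrix of that regression. Partial-mode standard errors deliberately ignore
stage-one propensity uncertainty, matching the Hessian-only description of
the method; `ttw_bootstrap_se()` offers a resampling check.

`mode = "full"` maximizes over all parameters jointly (BFGS started at the
partial solution, \(\sigma^2\) log-transformed, followed by Newton polishing
until the gradient sup-norm is at machine-noise level). The full optimum
always weakly dominates the partial one in likelihood.

For binary and count outcomes the bias term is placed additively on the
link scale of the observed-data regression,
\(g(E(Y|X,Z,R{=}1)) = X'\beta + \delta(X)(1-\pi)\). The original authors
describe alternatives (e.g. odds-ratio-scale homogeneity for logistic
models) in supplementary material that does not pin down a single form;
the link-additive form was chosen because it keeps all three families in
one estimating structure, and it is isolated behind the `family` argument
so an alternative parameterization could be swapped in without touching the
optimizer.

Identification requires the instrument: if the selection design adds no
column beyond the span of the outcome design, \((\beta, \eta)\) are
separable only through the nonlinearity of the logistic propensity, which
is numerically hopeless. `ttw_fit()` refuses such designs, and flags
near-collinearity of \([X, (1-\hat\pi)X]\) (condition number above 1e10)
as a weak-selection-instrument diagnostic rather than returning silent
garbage.

## Mendelian randomization adaptation

MR estimates are ratios or combinations of two regressions — the
instrument-exposure (G–X) and instrument-outcome (G–Y) associations. The
adaptation is compositional: whichever regression involves a masked
variable is replaced by a selection-adjusted fit, with selection design
\([1, G, Z]\) and Z always excluded from the outcome design. The fully
observed side stays OLS.

* `wald_ratio()`: \(\hat\theta = \hat\beta_Y / \hat\beta_X\) with the
  second-order standard error
  \(\sqrt{s_Y^2/\hat\beta_X^2 + \hat\beta_Y^2 s_X^2/\hat\beta_X^4}\).
* `tsls()`: two-stage least squares; an adjusted first stage produces
  fitted exposures free of selection bias for *all* individuals (G is fully
  observed), and an adjusted second stage handles masked outcomes. The
  textbook 2SLS variance is invalid as soon as any stage is adjusted —
  the package treats requesting it as a contract violation — and
  `tsls_bootstrap_se()` resamples individuals instead (the study design
  uses M = 100). Fully unadjusted (complete-case) 2SLS drops rows missing
  any variable used by either stage, matching the default behaviour of
  standard 2SLS implementations.
* `per_variant_summary_stats()` + `ivw()`: the adjustment is run once per
  variant to produce selection-adjusted summary statistics, combined by
  inverse-variance weighting. The default second-order weights plug the
  first-order estimate \(\hat\theta_1\) into
  \(1/(\sigma_{Yj}^2 + \hat\theta_1^2 \sigma_{Xj}^2)\), iterated once —
  the named second-order formula is not spelled out in the source
  literature, and a one-pass plug-in is the simplest member of that
  family. One-sample IVW triggers a sample-overlap warning rather than any
  correction.

## What the simulation engine emulates

`regression_scenario()` and `mr_scenario()` encode the study conditions:

* Regression baseline: \(Z, X, \epsilon \sim N(0,1)\),
  \(Y = 1 + 0.1X + \epsilon\), selection
  \(\mathrm{logit}\,\pi_R = \alpha_R + 0.5X + 0.4Z + 0.5Y\) with
  \(\alpha_R\) tuned so that half the outcomes are missing
  (\(\alpha_R = -0.5\) at baseline), \(n = 10^4\). Selection is generated
  from a *logistic* model while Heckman assumes probit — a deliberate
  working-model mismatch, kept as a designed stress test of the
  estimators' robustness. Variants flip one ingredient at a time:
  \(\beta = 0\), binary
  Z/X/Y, Poisson Y, selection driven by only X or only Y, and direct Z–X
  or Z–Y effects (the latter an exclusion-restriction violation).
* Single-instrument MR: \(G, Z, U, \epsilon_X, \epsilon_Y \sim N(0,1)\),
  \(X = \beta_X G + U + \epsilon_X\), \(Y = \theta X + U + \epsilon_Y\)
  with \(\theta \in \{0, 0.2\}\). \(\beta_X = \sqrt{2/19} \approx 0.324\)
  makes G explain exactly 5% of the exposure variance, since
  \(\beta_X^2/(\beta_X^2 + 2) = 0.05\) (the raw fraction 2/19 would
  explain only about 2%).
* Multi-instrument MR: K = 10 variants, allele frequencies
  \(f_j \sim U(0.1, 0.9)\), genotypes \(\mathrm{Bin}(2, f_j)\), effects
  from N(0, 0.05²) left-truncated at 0.15 (read as standard deviation
  0.05; together these again give about 5% explained variance). Effects
  and frequencies are redrawn each replication.
* Selection arms: (\(\beta_R, \delta_R\)) of (0, 1), (1, 0) and
  (0.5, 0.5) for outcome-, exposure- and jointly-driven selection, with
  \(\gamma_R = 0.5\) and the intercept tuned to 50% selection. Exactly the
  variables with nonzero selection effects are masked. Two-sample designs
  draw two independent samples and mask only the variable each sample
  measures — this is what makes the G–Y side estimable without bias when
  only the exposure drives selection.

`tune_alpha_R()` root-finds the intercept on a pilot sample of \(10^6\)
draws (tolerance 0.005 on the selection fraction, deterministic given its
seed) and returns the closed form \(\mathrm{logit}(p)\) when no variable
affects selection.

What the generator does *not* emulate: real genetic architectures
(linkage disequilibrium, weak and pleiotropic variants), covariate
measurement error, non-logistic selection, or interactions in the
selection model. Passing tests therefore demonstrate correctness of the
estimators under their assumed models and robustness to the
logistic-vs-probit mismatch — not performance on arbitrary real data.

## Numerical choices

* Probit and logistic first stages use IRLS (`stats::glm.fit`);
  (quasi-)complete separation is detected (near-zero deviance or
  unbounded linear predictors) and raised as an error, as is
  non-convergence.
* `heckman_ml()` parameterizes \(\rho = \tanh(a)\) and
  \(\sigma_1 = e^s\); BFGS with relative tolerance 1e-12 (maximum 500
  iterations) followed by Newton polishing. A fit with \(|\hat\rho|\)
  within 1e-6 of 1 carries a boundary warning.
* The bivariate-normal CDF behind `heckman_binary_ml()` is a 32-node
  Gauss–Legendre quadrature of the Drezner–Wesolowsky single-integral
  form, vectorized over observations and accurate to ~1e-12 for moderate
  correlations.
* The Mills-ratio column of the two-step fit can be exactly aliased with
  the outcome design (e.g. an intercept-only selection model). Pivoted QR
  then drops it with a warning and the slopes collapse to complete-case
  OLS; *near*-collinearity (condition number above 1e8) is an error
  advising that Z adds no exclusion information.
* All-selected data make the selection model vacuous; the fit degrades to
  OLS with a warning rather than an error.
* Monte-Carlo replication r uses seed `seed + r`, so runs are reproducible
  and individual replications can be re-examined in isolation. Failed
  fits within a replication set are excluded from the metrics and counted.

## Problem sizes

The packaged tests run the simulation study at desk scale: 2000
replications for the regression and single-instrument MR arms and 500
for the TTW arm and the multi-instrument arms (the full-scale design
uses 10⁴ and 10³, available by raising `n_reps`). These counts keep every
tabulated mean within the Monte-Carlo tolerance
max(3·SD/√reps, 0.005) used by the checks. The bootstrap for adjusted
2SLS standard errors is exercised at M = 30 in the tests (the study
setting is M = 100, available via `boot_M`).

## Known limitations

* Heckman's model has no Poisson-outcome variant (the TTW family covers
  counts); semiparametric relaxations of either estimator are out of
  scope.
* Partial-mode TTW standard errors ignore propensity-estimation
  uncertainty by construction.
* IPW is the simple benchmark version: logistic weights on fully observed
  columns, sandwich variance with weights treated as fixed; no doubly
  robust estimation.
* The IVW second-order variance is the one-pass plug-in described above;
  no overlap-bias correction is applied in one-sample use beyond the
  warning.
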