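---
title: "Model-implied simulation-based power estimation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-implied simulation-based power estimation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mspe)
```

## The problem

Power analysis for a single parameter of a latent-variable model rarely has
a closed form: the standard error of the focal estimate depends on the whole
model, the estimator, and the data distribution. The usual fallback is brute
simulation — pick a few sample sizes, simulate many datasets at each, count
significant tests — which is precise only at the chosen sample sizes and
interpolates poorly between them.

This package implements a parametric alternative for the z-test. For any
M-estimator, the focal estimate is asymptotically normal with standard error
`psi / sqrt(n)`, where `psi` is the square root of the focal diagonal
element of the sandwich covariance `H^-1 I H^-1` (`H` the expected Hessian
of the objective, `I` the variance of the scores). The z-statistic under the
alternative therefore has mean `|theta0| / psi * sqrt(n)`, and the power of
the one-sided level-`alpha` test is

```
P(significant | n)  ~  Phi(-q_{1-alpha} + |theta0|/psi * sqrt(n)).
```

This is exactly a probit regression of the significance indicator on
`sqrt(n)`, with asymptotic coefficients `beta0 = -q_{1-alpha}` and
`beta1 = |theta0|/psi`. So instead of estimating power pointwise, we simulate
significance decisions at many sample sizes (one replication per `n` is
enough), fit the probit-on-`sqrt(n)` model by maximum likelihood, and read
power at any `n` off the fitted curve. The required sample size for a target
power `rho` follows by inverting the link:

```
N = ceil( ((Phi^-1(rho) - beta0) / beta1)^2 ).
```

Because the fitted curve has sampling error, the package also reports a
lower-bound sample size `N_lb`: the smallest `n` whose `1 - alpha_rho`
confidence-band lower bound reaches `rho`. By construction
`P(N_lb < true N) ~ alpha_rho / 2`, which is the quantity a planner actually
wants to control — the risk of fielding an underpowered study.

For the two-sided test the significance probability is a two-term mean
function `Phi(beta0 + beta1 sqrt(n)) + Phi(beta0 - beta1 sqrt(n))` (the
"Wald" variant); no standard link matches it, so its likelihood is maximised
directly. Comparison methods with no such justification — probit/logit on
`n`, logit on `sqrt(n)`, and four-point linear interpolation ("naive") — are
included because the point of the probit-`sqrt(n)` link is precisely that
these alternatives are biased over ranges of `n`.

## Fitting and numerical choices

* **Probit/logit fits** use Newton–Raphson with step-halving on the
  log-likelihood, gradient tolerance `1e-8`, at most 100 iterations. The
  coefficient covariance is the inverse *observed* information at the
  optimum. Both coefficients are free; the deviation of `beta0` from
  `-q_{1-alpha}` is reported as a diagnostic of how closely the asymptotic
  theory holds at the simulated sample sizes.
* **Separation** (all decisions 0, all 1, or perfectly ordered by `n`) is
  detected before fitting and raised as a typed error telling the user to
  widen the `n` range; a power curve is only identified when both outcomes
  occur across the range.
* **The Wald fit** is seeded from the probit fit and maximised by
  box-constrained quasi-Newton with `beta1 >= 0`; a boundary solution
  `beta1 = 0` (flat curve at the test level) is flagged.
* **Confidence bands** for probit/logit are built on the linear-predictor
  scale (`eta_hat ± z_{1-alpha_rho/2} sqrt(x' V x)`) and mapped through the
  monotone response, which preserves coverage and keeps bands in [0, 1]. The
  Wald band uses a probability-scale delta method, clipped. The naive
  baseline attaches a per-grid-point normal interval
  `p ± z sqrt(p(1-p)/R_j)` (no continuity correction) and interpolates the
  lower bounds.
* **Inversion** uses the closed form where the link is invertible and
  monotone bisection on `n in [1, 1e7]` (power-scale tolerance `1e-6`,
  then ceiling) for the Wald mean function and for all lower-bound
  crossings; the two routes agree to the same integer for the probit
  (property-tested on random coefficients). If the target power is already
  attained at `n = 1` the inversion returns 1 rather than squaring a
  negative root. Targets are capped at `rho <= .99`: sample sizes fit in
  regions of near-unit power carry much larger uncertainty, and such
  targets are rarely meaningful in planning.
* Repeated `n` values are pooled in all parametric fits; the naive method
  requires exactly four distinct sample sizes.

Whether the lower-bound equation is evaluated by plugging estimated
coefficients into the closed form or by numerical search is immaterial for
the probit-`sqrt(n)` link (they coincide); the package uses the search
because it generalises unchanged to the Wald and naive curves. Likewise the
Wald variant estimates `beta0` freely rather than fixing it at
`-q_{1-alpha/2}`; the asymptotic value is reported as a diagnostic, not
imposed.

## The SEM engine

The built-in significance-decision generator fits covariance-structure
models by normal-theory ML: `Sigma(theta) = Lambda (I-B)^-1 Psi (I-B)^-T
Lambda' + Theta` in an all-latent parameterisation, minimising the ML
discrepancy with an analytic gradient (quasi-Newton, then damped Newton
polish to gradient norm `1e-6`). Identification is by the marker method —
the first loading of each latent fixed to 1, consistent with the generating
loadings `[1, .8, .7]`. The mean structure is omitted: double mean centering
removes the need for one. `Theta` is diagonal by default; correlated product
-indicator residuals can be freed explicitly but are off by default.

Standard errors: naive from the inverse observed information of the
casewise log-likelihood; robust ("MLR-style") from the sandwich
`H^-1 I H^-1`, with `I` estimated from casewise score outer products and
scores obtained by central finite differences of the casewise
log-likelihood (step `1e-6 * max(1, |theta_j|)`). On correctly specified
normal data the two agree (property-tested: median relative difference
below 5% at n = 1000).

Non-convergence is a taxonomy, not a warning: optimizer failure, a
non-positive-definite implied covariance, or a negative variance estimate
(Heywood case) each mark the replication non-converged with a reason code.
Such replications carry no significance information and are excluded from
power fits and reference frequencies; their rate is always reported, and a
study aborts if it exceeds 50%.

Latent interactions are estimated with the unconstrained product-indicator
approach: matched indicator pairs are mean-centered, multiplied, and the
products re-centered (so every product indicator has exactly zero sample
mean); the products measure one interaction factor (marker loading fixed,
free variance, free covariances with the interacting factors, free product
-indicator residual variances) and the interaction path is the focal
parameter. No nonlinear constraints are imposed, so the model is deliberately
a limited-information approximation — which is precisely why its power has
no analytic form and must be simulated.

## The synthetic-data generator

The generator emulates two study designs sharing one structural skeleton
(standardized latent variables, three indicators per latent with loadings
`[1, .8, .7]`):

* **Linear SEM**: `eta1 = .2 xi1 + .5 xi2 + zeta1`,
  `eta2 = .3 eta1 + .4 xi1 + .3 xi2 + zeta2`; focal parameter the path
  `xi1 -> eta1` (.2).
* **QISEM**: adds `.1 xi1*xi2` to the first equation; focal parameter the
  interaction (.1).

Residual variances of `zeta1`, `zeta2` are solved so all four latent
variables have unit variance — analytically under normal predictors (the
centered product is uncorrelated with the linear terms and has variance
`1 + phi12^2`), by a fixed-seed 1e6-draw Monte-Carlo evaluation of the
required moments under non-normal predictors (where odd cross-moments such
as `E[xi1^2 xi2]` no longer vanish).

Choices made where the design was open:

* The exogenous correlation `phi12` is not printed in the source design; it
  defaults to `.5` in the R API but the command-line interface requires it
  explicitly in the config.
* Indicator residual variances default to `.36` per indicator, giving
  coefficient omega ≈ .85 per scale. The reliability pair (omega = .85,
  H = .88) quoted for these loadings is not jointly attainable with equal
  residuals; rather than guess unequal residuals, the default is documented
  as approximate and per-indicator residuals are configurable.
* Kurtosis arguments are **excess** kurtosis throughout (the Vale–Maurelli
  literature convention).
* Non-normality can be placed on the latent predictors (the QISEM
  condition) or directly on the indicators (the linear-SEM manifest
  condition, implemented by targeting the model-implied indicator
  correlation matrix); the placement is an explicit config field.

Non-normal data use Fleishman cubic polynomials of standard normals with
the Vale–Maurelli intermediate-correlation solve (per-pair cubic solved by
`polyroot`, assembled matrix required to be positive definite — no silent
smoothing). The moment system is solved by Newton iteration to residual
`1e-10`, and solutions are verified against the closed-form moment
identities, not against tables. One target deserves emphasis: **(skewness
2.3, excess kurtosis 6.5) is not Fleishman-representable** — the minimum
excess kurtosis a Fleishman cubic attains at skewness 2.3 is about 7.26.
`fleishman_coefficients()` therefore refuses it by default. Because this
exact pair defines the second predictor of the shipped non-normal QISEM
condition, an explicit `allow_boundary = TRUE` opt-in returns the
least-squares boundary solution instead (unit variance held; achieved
skewness ≈ 2.21) with a warning stating the achieved moments. The shipped
condition uses the opt-in, so the generated second predictor is *near*, not
at, its nominal target; the first predictor's (1.7, 7.2) target is exactly
representable and is the one checked by the moment tests.

What the generator does **not** emulate: the Vale–Maurelli transform has a
normal copula, so passing moment checks says nothing about tail dependence
or other copula features of real data; indicators are continuous and
complete (no ordinal scales, no missingness); and the SEM engine fits
exactly the model class it simulates. Passing tests therefore demonstrate
internal calibration of the power machinery, not robustness to the many
ways real data deviate from these designs.

## Study orchestration and evaluation

`run_power_study()` allocates a replication budget over sample sizes
(uniform cycling over an integer grid, or four points with the remainder of
`R/4` assigned to the smallest), derives one RNG substream per replicate
from the master seed (so serial and parallel execution would agree), fits
all requested power models on the converged records, and inverts them.
Reference power at a fixed `n` is the relative frequency of significance
among converged replications with an exact Clopper–Pearson interval. The
evaluation criteria over repeated studies are bias and RMSE of the
estimated required sample size, bias of predicted power at the true
required sample size, and the type I proxy `P(N_lb < true N)`, expected
near `alpha_rho / 2`.

Desk-scale defaults are used throughout the tests: calibration of the
lower bound uses 2,000 studies of R = 550 idealized Bernoulli decisions
(the generating probit curve is the oracle, no SEM fitting needed);
moment checks use 1e6 draws; the z-test level check uses 1,000 ML fits at
n = 500; coverage uses 1,000 studies. Reference "truth" at this scale is
the closed-form inversion of the generating curve rather than millions of
SEM fits; the SEM-based reference remains available through
`estimate_reference_power()` at whatever replication count the user can
afford.

## Known limitations

* Only z-test power is modeled. Likelihood-ratio-test power is out of
  scope by design: the probit-`sqrt(n)` link is not an adequate model for
  the LRT under distributional misspecification, and scaled LRT statistics
  are not implemented.
* The probit power model is asymptotic in both `n` and `R`; at small `n`
  the normality of the focal estimate (hence the link) is an
  approximation, and the fit inherits whatever bias the z-test itself has
  there.
* The lower-bound calibration is itself asymptotic in `R`, and the ceiling
  to integer sample sizes can only make `P(N_lb < true N)` smaller than the
  continuous-scale nominal value — a mild conservative (safe-side)
  discretisation.
* Per-replicate seeds are drawn from the master-seeded generator rather
  than computed by an arithmetic map: linearly related seed sequences
  produce correlated first draws after reseeding, which measurably deflates
  within-study binomial variability and mis-calibrates the band.
* The SEM engine handles complete continuous data, diagonal residual
  covariance by default, no mean structure, and no categorical indicators;
  the sandwich uses finite-difference scores, which is accurate but not
  the fastest possible implementation.
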