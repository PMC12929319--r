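---
title: "Modelling longitudinal EQ-5D-3L utilities after kidney transplantation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling longitudinal EQ-5D-3L utilities after kidney transplantation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsuvlong)
```

## Why these models

EQ-5D-3L health-state utility values (HSUVs) scored with the French tariff
live on $[-0.53, 1.00]$. In kidney-transplant cohorts their distribution is
left-skewed, unimodal with a long lower tail, and carries a large point
mass at 1 (roughly 40% of questionnaires report full health). Repeated
questionnaires from one patient are correlated, and the trajectory has two
clinical phases: a rapid recovery during the first post-transplant year and
a slow decline afterwards. `hsuvlong` therefore fits four candidate
mixed-effects families on a common fixed-effect structure — intercept,
baseline covariates, and a piecewise-linear time basis
$t_\text{pre} = \min(t, 1)$, $t_\text{post} = \max(t - 1, 0)$ — and
compares them by precision (RMSE, MAE), prediction range, and decile
calibration. The knot is fixed at 1 year by default and configurable
(`knot`), since the changepoint is a clinical judgement rather than an
estimated quantity.

## The four families

Let $u_{ij}$ be the utility of patient $i$ at visit $j$, and
$\eta_{ij} = \beta_0 + x_i'\beta + \beta_\text{pre} t_\text{pre,ij} +
\beta_\text{post} t_\text{post,ij}$.

**Linear mixed model.** $u_{ij} = \eta_{ij} + b_{0i} + b_{1i}
t_\text{pre,ij} + \varepsilon_{ij}$ with independent
$b_{0i} \sim N(0, \tau_0^2)$, $b_{1i} \sim N(0, \tau_1^2)$,
$\varepsilon_{ij} \sim N(0, \sigma^2)$. The marginal likelihood is Gaussian
and evaluated exactly; per-patient Woodbury identities reduce it to small
sufficient statistics vectorized across patients, and the fixed effects are
profiled out by generalized least squares, leaving a 2–3 parameter
optimization. Random effects are independent by default because no
random-effect correlations are identified well enough at realistic
questionnaire counts (half the patients contribute a single visit).

**Mixed beta regression.** The decrement
$y = (u_\text{max} - u)/(u_\text{max} - u_\text{min})$ is compressed,
$y^* = (y(N-1) + 0.5)/N$ with $N$ the number of observations, so that
$y^* \in (0, 1)$ and a beta density applies:
$y^*_{ij} \sim \text{Beta}(\mu_{ij}\phi, (1-\mu_{ij})\phi)$ with
$\operatorname{logit}(\mu_{ij}) = \eta_{ij} + b_{0i} + b_{1i}
t_\text{pre,ij}$. The one-part model keeps the random slope for symmetry
with the linear model.

**Mixed two-part beta regression.** A zero decrement (utility exactly
$u_\text{max}$) is modelled by a mixed logistic regression with its own
random intercept ($\operatorname{logit} P_{0,ij} = \eta^z_{ij} + c_i$,
$c_i \sim N(0, \tau_z^2)$), combined with a mixed beta regression of the
positive decrements compressed with $N$ equal to their count. The zero-part
and conditional-part random effects are independent, so the two parts share
no parameters and are maximized separately; the reported log-likelihood,
AIC and BIC are for the joint model. Compression is applied only to the
positive part: compressing first would destroy the exact zeros that define
the ceiling state.

**Mixed ALDVMM.** On the utility scale, $K$ latent normal components with
means $\eta_{ij,c} + b_{0i}$ and SDs $\sigma_c$, mixed with probabilities
$\pi_c$; latent values above a near-ceiling threshold $\Psi_1$ are observed
as $u_\text{max}$ and values below $u_\text{min}$ as $u_\text{min}$,
which generates the boundary point masses. A single random intercept is
shared across components. $\Psi_1$ defaults to the largest attainable
tariff value strictly below $u_\text{max}$ when a value set is supplied
(0.9 otherwise). Class labels are made identifiable by sorting component
intercepts; the likelihood itself is invariant to permutations. Class
count is chosen by BIC (`select_aldvmm_classes()`); $K \ge 3$ is accepted
but flagged experimental because convergence is fragile at realistic
sample sizes.

## Estimation

Non-Gaussian families are estimated by marginal maximum likelihood with
adaptive Gauss–Hermite quadrature: per patient, the posterior mode of the
random effects is found by damped Newton iterations (vectorized across
patients), and the nodes are centred and scaled by the curvature at the
mode; two-dimensional effects use a tensor grid. The default is 9 nodes per
dimension (`nodes`), which agrees with 31 nodes to well below $10^{-3}$
log-likelihood units on cohorts of this shape; a minimum of 5 is enforced.
Optimization is quasi-Newton (`nlminb`) on an unconstrained scale (log SDs,
log $\phi$, multinomial logits for $\pi$) with the score computed
analytically as the posterior-weighted complete-data score at the
quadrature nodes, and the design matrix standardized internally to
condition the Hessian (estimates are mapped back exactly). The ALDVMM uses
seeded multi-start (default 10 starts) around a linear-mixed-model fit.
Standard errors come from the numerically differentiated observed
information at the optimum.

Two independent checks are built into the test suite: the quadrature path
reproduces the closed-form Gaussian marginal likelihood to $10^{-6}$, and a
one-class ALDVMM with inactive censoring reproduces the linear mixed fit;
the zero part and the beta part are additionally cross-checked against
`lme4::glmer` and `glmmTMB` on common data.

## Covariate selection

Following standard epidemiological practice the package screens each
candidate covariate one at a time against the base model (time basis +
random effects) with a likelihood-ratio test at $p < 0.20$, then adds
screened candidates by forward selection at $p < 0.05$, smallest p-value
first, ties broken by candidate order. Candidates only ever enter the fixed
effects (both parts, df = 2, for the two-part family), so the
$\chi^2$ reference applies. Selection is run per family.

## Evaluation

Precision metrics and calibration are computed on fixed-effect-only
predictions (random effects at zero): the reported errors describe what the
model predicts for a *new* patient with given characteristics, not the
within-sample patient-specific fit. Calibration groups observations by
deciles of the predicted values (stable ranks), regresses the ten observed
group means on the ten predicted means, and flags aberrant deciles by
externally studentized residual $|r| > 2.5$ or Cook's distance $> 0.5$ on
the ten-point regression, excluding at most two and refitting once. The
thresholds are package choices: the diagnostics are standard, published
analyses name them without thresholds, and this rule isolates a single
planted outlier on constructed fixtures while leaving a numerically perfect
identity line untouched. The calibration regression is unweighted.
Evaluation is within-sample by default, matching how such models are
reported; `predict()` + `precision_metrics()` support any held-out split.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure of a large French multicentric
transplant cohort (2,787 adult recipients, 5,679 questionnaires): covariate
distributions match the published baseline table (age 50.0 ± 14.2
truncated to 18–90, 63% men, BMI < 18/18–30/> 30 at 4.3/83.7/12.0%,
diabetes 13.6%, cardiovascular disease 34.5%, neoplasia 11.5%, hypertension
86.6%, first graft 85.3%, relapsing nephropathy 28.1%, dialysis years as a
moment-matched gamma with mean 2.5 and SD 3.3, donor age 51.6 ± 15.7);
questionnaire counts follow the published 51.3%/22.7%/25.9% split for
1/2/≥ 3 with a geometric tail (ratio 0.6, capped at 10); visit times are
i.i.d. truncated-exponential (mean 4 years, range 0.08–29.5), a calibration
chosen to reproduce three published facts (19.9% of questionnaires within
the first year, maximum 29.5 years, median latest completion near 5 years)
rather than a claim about the true visit process. Outcome parameters
default to the published linear and two-part coefficient tables; the beta
precision $\phi$ defaults to 5 (not published; recovery tests always
compare to the configured value). Comorbidities are generated independently
because their correlations are not published.

Design choices worth knowing:

* Linear-family outcomes are **not clamped** to $[-0.53, 1]$ by default, so
  maximum likelihood is exactly consistent in recovery studies; a
  `clamp = TRUE` option exists for realism.
* Beta-family outcomes are drawn **on the compression scale** and the
  compression inverted, so a refit sees exactly beta-distributed values.
  Draws below $0.5/N$ (about 0.4% under the default J-shaped conditional
  density) cannot be represented on that scale and are censored upward;
  this leaves a small downward bias in the recovered conditional variance
  components (about 0.07 on an SD of 0.77) and is the price of emulating a
  discrete-grid outcome with a continuous law. Real EQ-5D data have no mass
  in that region, so the limitation is specific to the synthetic set-up.
* `discretize = TRUE` snaps interior utilities onto the attainable grid of
  a supplied value set, reproducing the granularity of tariff-scored data.

What passing recovery tests on these cohorts shows: the estimation
machinery maximizes the right likelihood at the study's scale and the
selection/evaluation pipeline behaves as specified. What it cannot show:
that any family is correctly specified for real transplant cohorts, or how
the models behave under informative drop-out (return to dialysis, death),
which the generator does not simulate.

## Scale of the shipped simulations

The packaged acceptance study uses five seeds at the full study size
(2,787 patients, ≈ 5,900 questionnaires per seed) for both the linear and
two-part recovery harnesses — a linear fit takes well under a second and a
two-part fit about half a minute — and 250 replicates at 300 patients for
the null calibration of the univariate screen. Medians across seeds are
compared against the published 95% confidence intervals.

## Value sets

Tariff coefficients are never shipped: `read_value_set()` loads any
additive 3L tariff (per-dimension level-2/level-3 decrements plus optional
any-problem and any-level-3 constants) from a small YAML file, which covers
the common European 3L tariff structures. `enumerate_grid()` scores all
243 profiles to expose the attainable utility grid, used for the default
$\Psi_1$ and for discretization.

## Known limitations

* Random-effect correlations are not estimated (none are published to
  anchor them); the two-part model's parts are independent by construction.
* The ALDVMM omits covariates in the class-membership probabilities and is
  validated for $K \le 2$ only.
* Post-transplant (time-varying) covariates are out of scope; only baseline
  characteristics enter the models.
* Within-sample evaluation inherits the usual optimism of apparent
  performance; the package provides the pieces for external validation but
  no resampling machinery.
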