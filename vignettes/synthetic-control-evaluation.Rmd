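---
title: "Evaluating a single-unit policy with synthetic controls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating a single-unit policy with synthetic controls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthgap)
```

## The problem

A policy is piloted in a single region — here the motivating setting is a
drug-pricing reform piloted in one prefecture-level city, with the outcome
measured as the drug share of per-visit medical cost (percentage points) —
and a dozen untreated regions are observed over the same years. With one
treated unit and a handful of annual observations, regression-based
inference is fragile, and a plain treated-vs-average contrast assumes the
treated unit would have tracked the donor average absent the policy. The
synthetic control method replaces that assumption with an explicit
construction: a convex combination of donors chosen so that the combination
reproduces the treated unit's *pre-policy* outcomes and covariates. Its
post-policy trajectory is then the counterfactual.

## Model and estimator

Index units by $j = 1, \dots, J+1$ with $j = 1$ treated, and years by $t$.
The synthetic outcome is

$$\hat{Y}^N_{1t} = \sum_{j=2}^{J+1} w_j Y_{jt}, \qquad
  w_j \ge 0, \; \sum_j w_j = 1,$$

and the per-year effect estimate is the gap
$\hat{\alpha}_{1t} = Y_{1t} - \hat{Y}^N_{1t}$. The package summarizes the
effect as the mean post-policy gap, optionally expressed relative to the
outcome level in the last pre-policy year.

Weights solve a nested problem. The inner problem picks $W$ to minimize the
matching distance
$(X_1 - X_0 W)' V (X_1 - X_0 W)$
over the probability simplex, where $X_1$ ($k \times 1$) and $X_0$
($k \times J$) stack the predictors: each covariate's pre-policy mean and
the outcome in each pre-policy year. This is a convex quadratic program,
solved by an active-set method (`pracma::quadprog`) with a $10^{-9}$-scaled
ridge so that rank-deficient Hessians ($k < J$) stay numerically positive
definite; feasibility ($w_j \ge 0$, $\sum w_j = 1$ within $10^{-8}$) is
re-verified on every solution, and an infeasible return is an error rather
than a silent repair.

The outer problem picks the diagonal importance matrix $V$ (nonnegative,
normalized to sum to one). The matching distance says how much each
predictor counts; nothing in the data pins $V$ down a priori, so
`optimize_importance()` follows the standard data-driven practice: choose
$V$ to minimize the pre-policy mean squared prediction error (MSPE) of the
implied synthetic outcome path. The search runs on a softmax
parameterization of the simplex with $k-1$ free coordinates (the first
log-ratio is pinned at zero so the parameterization has no flat direction),
Nelder–Mead from the equal-weights start plus seeded random restarts
(Brent's method when $k = 2$ makes the problem one-dimensional), and a final
sweep over the $k$ vertex candidates $V = e_i$, because boundary optima can
only be approached asymptotically through a softmax. `v = "equal"` skips the
nested step entirely and is used throughout the calibration simulations,
where speed matters and predictor weighting is not the quantity under test.

### Predictor standardization

The predictors mix persons (population), currency (GDP per capita, medical
operation expenses) and percentages; an unstandardized distance would be
dominated by whichever predictor has the largest raw variance. Each
predictor row is therefore centered and scaled across the $J+1$ units before
optimization. Balance tables report the raw scale, and the standardization
record is kept in the fit. A useful consequence: adding a constant to every
unit's outcome leaves the weights unchanged and shifts the synthetic path by
the same constant, so the gap series is level-invariant.

### Donor-level adjustment

When the treated unit sits persistently below (or above) every donor — in
the motivating study the treated city's inpatient drug share ran about 10
points below the rest of the province — no convex combination can reach its
level and the pre-policy fit degrades beyond use. `adjust_donor_level()`
shifts every donor's outcome by a fixed offset (additive percentage points
by default; a relative rescale mode is available because a phrase like
"reduced by 10%" admits both readings). The adjustment is recorded in the
panel's metadata and surfaces in every downstream report, and it is exactly
invertible. `fit_synthetic_control()` warns when the pre-policy MSPE exceeds
`poor_fit_mspe` (default 10 pp², i.e. RMSE ≈ 3.2 pp) — comfortably above
what year-to-year noise produces at this scale and far below the MSPE seen
when the treated unit is structurally out of reach — as a hint that such an
adjustment (or a different donor pool) is needed.

## Placebo inference

With one treated unit there is no sampling-based standard error worth
reporting; inference is permutation-style. `run_placebo()` reassigns
treatment to each donor in turn, refits with the identical predictor
specification, and compares the treated unit's effect (absolute mean
post-policy gap) with the placebo distribution. Two conventions needed
fixing where practice varies:

* **Exclusion rule.** A placebo unit whose pre-policy MSPE exceeds
  `ratio_threshold` (default 5) times the treated unit's is excluded —
  strictly greater than, exactly as the rule is usually worded. A huge
  placebo "effect" on top of a terrible pre-policy fit is lack of fit, not
  signal.
* **Pseudo p-value.** The proportion of *retained* placebo units at least
  as extreme as the treated unit. The treated unit is not self-counted, so
  with 12 donors, 2 excluded and 1 as-extreme the value is exactly 1/10.
* **Placebo donor pools.** By default the genuinely treated unit is dropped
  from every placebo pool so the real treatment cannot leak into placebo
  counterfactuals. `include_treated_in_pools = TRUE` keeps it — the right
  choice in null simulations, where it makes all units exchangeable and the
  treated unit's effect rank exactly uniform.
* **Effect statistic.** Extremeness is judged on the mean post-policy gap
  magnitude, matching how placebo effects are usually displayed; a post/pre
  MSPE-ratio statistic is a known alternative and is deliberately not the
  default.

## DiD cross-validation

`fit_did()` estimates
$Y_{it} = \gamma + \beta_1 \mathrm{Treat}_i + \beta_2 \mathrm{Post}_t +
\beta_3 \mathrm{Treat}_i\mathrm{Post}_t + b X_{it} + \epsilon_{it}$
by OLS, with covariates entered as raw yearly values and the effect read
off $\beta_3$. The model is implemented exactly as written — no unit or
year fixed effects beyond the two dummies. Classical standard errors are
the default, matching the homoskedastic error term in the model as stated;
cluster-robust-by-unit is available by flag, with the caveat that ~13
clusters make cluster-robust inference noisy (in our own calibration its
95% CI covers a true constant effect far less often than the classical CI,
whose coverage is on target once the covariates absorb the unit effects).
The DiD route exists as a cross-check: it leans on parallel trends, which is
precisely what the synthetic control relaxes, and under the factor DGP below
its bias visibly exceeds the synthetic control's.

## The synthetic data generator

`generate_panel()` draws city-year panels from an interactive-fixed-effects
model

$$Y_{jt} = \theta_t + \mu_j + \lambda_t f_j + \tau_t D_{jt}
           + \delta \cdot 1[j = 1] + \varepsilon_{jt},$$

defaulting to the study's dimensions: 13 units, years 2008–2015, treatment
from 2013 — five pre-policy and three post-policy years. The factor term
$\lambda_t f_j$ makes unit trends diverge, which is the world in which the
synthetic control's premise (time-varying unobserved factors) is meaningful
and in which a DiD-vs-SCM contrast is informative; `parallel_trends = TRUE`
collapses the loadings to recover a parallel-trends world for DiD checks.
Defaults: effect $\tau = -7.7$ pp (the scale of the motivating outpatient
estimate), noise $\sigma = 1$ pp, unit-effect spread 2.5 pp, loadings
uniform on [0.7, 1.3], common level drifting down from 48 pp. The six
covariates are affine in $(f_j, \mu_j)$ plus a loading-linked time trend and
noise proportional to $\sigma$, calibrated to plausible magnitudes
(urbanization 50–70%, elderly share 18–28%, GDP per capita 40–80k, life
expectancy 77–82 years, operation expenses 150–300, population 3–8M). Three
seeded scenarios are canned in `make_study_fixture()`: a clear negative
effect with the treated unit level-comparable to donors
("outpatient-like"), a treated unit sitting 10 pp below its pool with a
smaller effect ("inpatient-like", $\delta = -10$, $\tau = -3.2$,
$\sigma = 0.5$), and a null.

Two constructions exist purely to make estimator guarantees testable: at
$\sigma = 0$ the covariate noise also vanishes, so covariates are exact
affine functions of the latent structure; and `treated_in_hull = TRUE`
places the treated unit's $(f, \mu)$ at a known convex combination of the
donors', so a perfect synthetic control exists by construction and constant
effects are recovered to numerical precision.

What the generator does *not* emulate: serially correlated shocks, outcome
autocorrelation beyond the factor structure, covariate measurement error
correlated with treatment, staggered adoption, or any attempt to mimic the
actual provincial values beyond magnitude calibration. Passing tests on
these panels show the estimators do what they claim under a factor DGP at
study scale — not that any particular real-world estimate is right.

## Numerical choices

* QP ridge $10^{-9} \times$ mean Hessian diagonal; solutions with
  $w_j < -10^{-7}$ are clipped to zero and renormalized, anything worse is
  an error.
* Weights below 0.001 are *displayed* as "~ 0" (a common reporting
  convention) but stored at full precision.
* Tied optima (duplicate donors) return an arbitrary optimal vertex; tests
  assert the objective, never the weight vector, in tied cases.
* Displayed percentages are rounded to one decimal only in human-readable
  report fields; machine outputs carry full precision.
* All randomness (generator, restarts) flows through explicit integer
  seeds; identical configuration means byte-identical output files.
* Verification problem sizes, chosen to keep the full suite in a few
  minutes of one CPU: solver-vs-grid equivalence on 100+ random instances
  (donor pools of 2–4; exhaustive grids at step 0.001, refined to $10^{-5}$
  and $5\times10^{-4}$ for the two-sided comparison, since a 0.001 grid's
  own discretization error can exceed the $10^{-6}$ agreement band); effect
  recovery over 100 seeded replicates; placebo rank calibration over 200
  null replicates; DiD coverage over 100 replicates.

## Limitations

Single treated unit only — no multiple-treated aggregation, no in-time
placebos, no augmented/penalized synthetic-control variants, no
leave-one-out donor jackknife. The pseudo p-value's resolution is limited
by the donor count (with 10 retained placebos it moves in steps of 0.1).
The nested $V$ search is a local method with restarts, not a global
certificate; with many predictors it can in principle settle on a local
optimum, which is why the equal-weights fit is always available as a
transparent baseline.
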