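---
title: "Shared dose-measurement error: model, estimators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared dose-measurement error: model, estimators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
dose-error model and its assumptions, the estimators and their numerical
details, the choices made where the design was genuinely open, and what
the simulation does and does not capture about real data.

## The composite error model

Dose uncertainty is modelled as multiplicative lognormal error around a
grouped dose structure. A cohort is divided into dose groups (five by
default, with boundaries 0–0.07, 0.08–0.19, 0.20–0.99, 1.00–2.49 and
≥ 2.50 Gy); each group carries a central dose estimate, a person-year
offset and a number of simulated individuals. Within one
*meta-simulation*, `m` *sub-simulations* are drawn; individual `i` of
group `k(i)` receives in sub-simulation `j`

$$D_{\mathrm{true},i,j} = D_{\mathrm{cent},k(i)}\,
  e^{-\tfrac12(\sigma_{sB}^2+\sigma_{uB}^2)}\,
  e^{\sigma_{sB}\varepsilon_j + \sigma_{uB}\delta_{i,j}}, \qquad
  D_{\mathrm{surr},i,j} = D_{\mathrm{cent},k(i)}\,
  e^{-\tfrac12(\sigma_{sC}^2+\sigma_{uC}^2)}\,
  e^{\sigma_{sC}\mu_j + \sigma_{uC}\kappa_{i,j}},$$

with all noise draws iid standard normal. The draws
$\varepsilon_j,\mu_j$ are *shared*: one value per sub-simulation, common
to every individual, so they model system-wide dosimetry biases that do
not average out over a cohort. The draws $\delta_{i,j},\kappa_{i,j}$ are
*unshared* (independent per individual). The exponential prefactors make
every dose mean-one around its central estimate, so the error model is
unbiased by construction. Berkson components perturb the *true* dose
around the assigned value; classical components perturb the *surrogate*
around the truth and therefore only ever reach the unadjusted estimator.

The four log-scale SDs are dimensionless; a value of 0.2 is a geometric
SD of exp(0.2) ≈ 1.22, conventionally labelled a "20%" error, and the
study scenarios use 0, 0.2 and 0.5.

Pairwise consequences are analytic and are used as test oracles: two
individuals' true-dose series across sub-simulations have correlation
$(e^{\sigma_{sB}^2}-1)/(e^{\sigma_{sB}^2+\sigma_{uB}^2}-1)$, which is
exactly 1 when the unshared component vanishes. The reported correlation
averages 100 random distinct pairs under a fixed seed; the pairing
protocol is this package's choice, and with hundreds of sub-simulations
the choice is immaterial at the reported precision.

## Case generation

Cancer cases (default N = 250 per meta-simulation) follow a single
multinomial draw over individuals with probabilities proportional to the
excess-relative-risk model $RR(d) = 1 + \alpha d + \beta d^2$ evaluated
at each individual's true doses and *averaged over the m
sub-simulations*. The same case vector is shared by all sub-simulations
of the meta-simulation. Averaging the relative risk (rather than drawing
cases anew per sub-simulation) is the reconciliation of two readings of
the protocol — a per-sub-simulation case probability versus a case
distribution held constant within each meta-simulation — and we follow
the constant-distribution reading: dose uncertainty should not multiply
the outcome randomness.

True coefficient values used throughout the scenarios:
linear-quadratic $\alpha = 0.25$/Gy, $\beta = 2$/Gy²; linear
$\alpha = 3$/Gy. Both satisfy $RR > 0$ over the grid support, which the
scenario constructor enforces.

### The default grid

The exact central doses and person-year distribution of the reference
cohort are not published alongside the group boundaries, so the defaults
here are the package's own calibration, chosen once: central doses
(0.02, 0.12, 0.45, 1.5, 2) Gy — close to person-year-weighted group
means of a Life Span Study-like cohort, with the top group pinned at
2 Gy — and person-year proportions (0.702, 0.110, 0.130, 0.040, 0.017).
Simulated individuals (default 1000) are allocated to groups by largest
remainder proportionally to person-years, and the Poisson offsets are
set equal to those cohort counts so that the multinomial case generator
and the Poisson fit describe exactly the same exposure structure. Every
piece of this is overridable from the steering file.

## Fitting: Poisson linear relative risk

Grouped data are fitted with rates
$\mu_g = e^{\kappa} PY_g (1+\alpha d_g + \beta d_g^2)$, maximising
$\sum_g [y_g \log \mu_g - \mu_g]$ (constants dropped) subject to
$RR(d_g) > 0$ at every observed dose. Numerical choices:

* The intercept is profiled analytically —
  $e^{\hat\kappa} = \sum y_g / \sum PY_g RR_g$ — reducing the search to
  one dimension (linear) or two (linear-quadratic). This sidesteps the
  ridge between intercept and slope that makes joint Newton steps
  fragile with five data points.
* The linear-form search uses a coarse scan plus golden-section polish
  on the feasible interval $\alpha > -1/\max(d)$; the quadratic form
  uses Nelder–Mead with a large finite penalty outside the positivity
  region and a restart from the first solution.
* Confidence intervals are profile-likelihood: the set of values whose
  profile log-likelihood is within $\chi^2_1(0.95)/2 = 1.92$ of the
  maximum, located by geometric bracket expansion from the MLE followed
  by bisection to $10^{-6}$ on the log-likelihood scale. Bounds cut off
  by the positivity constraint are flagged `"boundary"`; sides on which
  the profile never drops are flagged `"unbounded"`. If all group doses
  are equal the slope is unidentifiable and the fit refuses with an
  explicit error rather than returning a flagged answer.
* AIC is $-2\ell + 2p$ with $p$ the number of free parameters (2 or 3).
  Because additive constants are dropped consistently, AIC *differences*
  — all any weighting uses — are exact.

The inner likelihood kernels are compiled (C++) because the
model-averaging estimators evaluate them $10^4$–$10^6$ times per
meta-simulation.

## The five estimators

**Unadjusted** fits the surrogate-dose group means from one designated
sub-simulation. One realisation — not an average over sub-simulations —
is essential: averaging surrogates would cancel exactly the classical
error whose effect this estimator exists to display.

**Regression calibration** substitutes the conditional expectation of
true dose given group membership: group means of true doses over
individuals and sub-simulations.

**Monte Carlo maximum likelihood (MCML)** maximises the averaged
likelihood $L(\theta) = \tfrac1m \sum_j L(\theta;\text{vector } j)$ over
the per-sub-simulation group-mean dose vectors, with profile intervals
on the same averaged likelihood. The arithmetic mean of likelihoods (not
of log-likelihoods) is the standard Monte Carlo likelihood for shared
error, and it degenerates correctly: one vector reproduces the plain
fit, identical vectors reproduce regression calibration. The reference
formulation this mirrors is published only in outline, so the averaged
form here is a documented interpretation.

**Quasi-2DMC with Bayesian model averaging** samples the mixture
posterior $\sum_k p_k\, p(\theta \mid Y, D_k)$ with softmax weights
$p_j = e^{\lambda_j}/(1+\sum_k e^{\lambda_k})$ (the m-th category is the
reference). Protocol: alternating Metropolis–Hastings — scalar updates
of $\kappa, \alpha, \beta$ against the mixture likelihood given the
weights, then $\lambda$ in fixed sequential blocks of 10; N(0, 1000²)
priors on everything; proposal SDs 0.2 ($\kappa$), 1 ($\alpha,\beta$), 2
($\lambda$); two chains, 1000 burn-in, 1000 kept. Block order and the
equal-tailed 2.5/97.5 credible interval are this package's choices where
the protocol is silent. Convergence is monitored with the
Brooks–Gelman–Rubin potential scale reduction factor computed from the
second half of each chain's kept draws; a summary with any parameter
above the threshold (default 1.05) is flagged, and flagged summaries
stay in coverage denominators and in mean-coefficient cells (the flag is
a mixing diagnostic, not an invalidation, and full-scale protocols
average all datasets). Proposals under which every mixture component's
relative risk is non-positive have zero posterior density and are
rejected; a component that is individually infeasible simply contributes
zero to the mixture.

**Frequentist model averaging (FMA)** fits every dose vector by maximum
likelihood, recovers a per-fit SD from the profile interval as
$\min(\hat\theta - \ell, u - \hat\theta)/1.96$, draws k = 100 normal
samples per coefficient per fit, and pools them with AIC weights
$e^{-AIC_j/2} / \sum_k e^{-AIC_k/2}$ — note the negative sign, so
better-fitting vectors get larger weight (the opposite sign, which
demonstrably up-weights worse fits, appears in the literature as a
misprint and is exercised in the tests only to show it is wrong). The
maximum AIC is subtracted before exponentiation so the weights never
overflow. The central estimate is the weighted mean of the pooled
samples; the interval is their weighted 2.5/97.5 centiles. Vectors whose
fit does not converge (or whose recovered SD is not finite) are dropped
and counted rather than imputed — the weighting presumes valid AICs. An
asymmetric-SD variant (separate SDs from the two CI arms) exists behind
`symmetric_sd = FALSE`; it is off by default because occasional very
wide CI arms make it badly behaved.

## Evaluation

For each scenario the harness reports, per method and coefficient:
coverage of the 95% intervals (non-converged ML fits remain in the
denominator and are reported), ensemble-mean coefficients with
percentage bias $100(\bar\theta/\theta - 1)$, and percentage bias in
predicted ERR at 0.1 and 1 Gy computed from the *mean* coefficients
(not the mean of per-dataset biases — the two differ, and the
ratio-of-means form is the quantity the tables define). The ERR-bias
measure is invariant to common rescaling of coefficients and truth,
which the tests exercise as a property.

Ensemble sizes: the package defaults to desk-scale runs of
n_meta = 100–200 meta-simulations × m_sub = 100 sub-simulations, with
binomial coverage noise ±1.5–3 percentage points; the full-scale
protocol (500 × 1000) is available through the steering file or the
CLI's `--scale paper`. The test suite's scenario reproductions use the
desk scale and 3σ binomial/Monte-Carlo tolerances.

## Reproducibility

Every scenario derives one seed per meta-simulation from its master
seed up front; estimator-level seeds are drawn unconditionally within
each meta-simulation so the stream does not depend on which methods are
requested. Runs are bit-for-bit reproducible, serial or parallel, and
the C++ sampler uses R's own RNG so `set.seed()` governs everything.

## What the generator does and does not emulate

It emulates: grouped exposure with realistic person-year weighting, the
full shared/unshared × Berkson/classical error taxonomy, fixed total
case counts, and the nested two-dimensional (meta/sub) uncertainty
structure. It does not emulate: covariate stratification (age, sex,
city), dose-dependent error magnitudes, differential or non-lognormal
error, secular follow-up structure, or real-data artefacts such as dose
truncation. Passing tests therefore demonstrate correct behaviour of
the estimators under the stated error model, not performance on any
particular real cohort.

## Known limitations

* With five dose groups and 250 cases the linear-quadratic MLE is
  strongly finite-sample biased (the two coefficients trade off along a
  constrained ridge), and the direction and size of that bias depend on
  the grid calibration. Mean-coefficient comparisons across differently
  calibrated grids should be read with that in mind.
* Under large shared Berkson error the mixture posterior of the BMA
  estimator is nearly flat across candidate dose vectors whose scale
  differences are absorbed by the coefficients; its λ-random-walk then
  mixes slowly, the BGR flag fires frequently at desk scale, and
  posterior summaries for the linear-quadratic form are wide rather
  than collapsed. The package reports the diagnostic honestly instead
  of forcing agreement with any particular published behaviour of this
  estimator family.
* Extended regression calibration is deliberately out of scope; the
  estimator registry (`register_estimator()`) is the plug-in point for
  it and for any external method.
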