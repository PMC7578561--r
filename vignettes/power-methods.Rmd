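---
title: "Simulation-based power for interrupted time series vaccine studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-based power for interrupted time series vaccine studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## Why simulate power for an ITS analysis?

Interrupted time series designs estimate a vaccine effect from a single
monthly count series by contrasting the period after introduction with the
extrapolated pre-vaccine pattern. Closed-form power formulas do not exist
for this setting: power depends jointly on the mean count level, the shape
and strength of seasonality, any secular trend, the overdispersion of the
counts, the number of baseline years, and the size and speed of the decline
to be detected. The practical alternative is conditional simulation — take
the observed pre-vaccine series as fixed, learn its statistical
characteristics, generate many plausible post-vaccine futures with a known
effect injected, and count how often the analysis model finds it. That is
what `itspower` implements, as a best-case assessment: the estimation model
and the generating model coincide, so real-world power will usually be
lower.

## The baseline model

`fit_baseline()` fits

$$Y_t \sim \mathrm{Poisson}(e^{\mu_t + \phi_t}), \qquad
  \phi_t \sim N(0, \sigma^2),$$

$$\mu_t = \beta_0 + \beta_1 t + \beta_2 \cos(2\pi t/12) +
  \beta_3 \sin(2\pi t/12) + \beta_4 \cos(2\pi t/6) + \beta_5 \sin(2\pi t/6),$$

with $t$ the 0-based month index. The 12- and 6-month cosine/sine pairs
capture smooth annual seasonality; the linear term captures secular trend;
$\phi_t$ is an observation-level random intercept whose SD $\sigma$ is the
model's operational measure of *unexplained variability* (all power
summaries are reported against it). The $t$ origin is an internal
convention: rescaling it moves $\beta_0, \beta_1$ but not any rate ratio.

Control series (e.g. non-respiratory hospitalizations) can enter two ways:

- `control_mode = "covariate"`: each control joins the design as
  $\log(\text{count} + 0.5)$ — multiplicative confounding on the log-link
  scale, with $+0.5$ guarding zero months; its coefficient is estimated,
  which down-weights controls that do not track the outcome.
- `control_mode = "offset"`: a single control enters as a fixed
  $\log(\text{count})$ offset (coefficient pinned to 1), which guarantees
  the shared trend is removed but transfers any artefact in the control
  directly into the outcome model. Zero months are an error here, since the
  offset would be $-\infty$.

### Likelihood and optimization

With an observation-level random effect the marginal likelihood factorizes
into one-dimensional Poisson-lognormal integrals, one per month. Each is
evaluated by **adaptive Gauss-Hermite quadrature** (default order 25): the
quadrature rule is recentred at the posterior mode of $\phi_t$ (found by a
few Newton steps; the integrand is strictly log-concave) and rescaled by
the local curvature. Plain, uncentred quadrature concentrates its nodes
around $\phi = 0$ and loses many digits whenever a count pulls the
integrand several prior SDs away; the adaptive rule keeps the error below
$10^{-6}$ per observation across the whole plausible range (verified in the
test suite against an independent adaptive-integration oracle). All sums
use log-sum-exp; at $\sigma = 0$ the likelihood reduces exactly to the
plain Poisson one, continuously.

Maximization is over $(\beta, \log\sigma)$ jointly with analytic gradients
(posterior-expectation form of the score), initialized at the Poisson GLM
solution and $\log\sigma = \log 0.1$, using L-BFGS-B with $\log\sigma$
bounded in $[-10, 3]$. Estimation is full ML: like any ML variance
component, $\hat\sigma$ carries a small $O(p/n)$ downward bias (about 4%
at $n = 120$ months with 6 regressors; `lme4::glmer` shows the same on the
same data), which is immaterial for power but visible in high-precision
recovery experiments. The Wald covariance of $\hat\beta$ is the inverse
observed information at the optimum, conditional on $\hat\sigma$ — the
convention mixed-model software reports — and $\sigma$'s own uncertainty is
deliberately not propagated into simulation: replicates use $\hat\sigma$ as
a point value.

A non-convergent optimizer is recorded (`converged = FALSE`) rather than
raised; the power engine excludes such replicates from the power
denominator and reports them in `n_failed`.

## Simulating post-vaccine futures

For each replicate, `simulate_post()`:

1. draws one coefficient vector from $MVN(\hat\beta, \widehat{\mathrm{vcov}})$
   (one draw per replicate — parameter uncertainty; $\phi_t$ is drawn fresh
   each month — unexplained variability; the Poisson draw adds observation
   noise);
2. computes $\mu_t$ from the post-period design, whose time index and
   harmonic phase continue the baseline numbering;
3. adds the vaccine ramp $v_t = \min(t, r)/r \cdot \log(\mathrm{IRR}_f)$,
   where $t = 0$ is the introduction month and $r$ is `ramp_months`
   (default 24; `ramp_months = 1` yields a step change, appropriate for
   campaigns);
4. draws $Y_t \sim \mathrm{Poisson}(e^{\mu_t + \phi_t + v_t})$.

The simulated post period is concatenated with the observed baseline
(`assemble()`), bit-identical, so all power statements are conditional on
the data actually seen. The introduction month itself carries ramp value 0
— the decline begins the following month. The mirrored estimation spline
uses the same convention; the alternative (counting the introduction month
as 1) shifts results by at most one month of ramp and is noted as an
ambiguity of the design.

Control series are not modelled forward: absent user-supplied post-period
controls, each control's seasonal profile (mean per calendar month over the
last three baseline years, rounded) is repeated across the evaluation
period. This is a documented package choice — adequate for controls whose
role is seasonal/level adjustment, too rigid if the control itself trends
strongly; users with a real post-period control should pass it explicitly.

## Estimating the effect

`fit_its()` refits the same Poisson-lognormal model to the combined series
with one extra column: a linear spline that is 0 before introduction and
rises to `ramp_months`, then stabilizes. The log rate ratio at ramp end is
`ramp_months * beta_v` — the spline coefficient is a per-month log-rate
change, so the printed rate ratio is its exponential
(`exp(ramp * beta_v)`), with the 95% Wald interval mapped through the same
monotone transform (exact by the delta method, since the transform is
linear in `beta_v`). Significance is the two-sided interval excluding 1.
If the evaluation period is shorter than the ramp the ramp-end rate ratio
is a slope extrapolation and the estimate carries `extrapolated = TRUE`.

## The power engine

`run_power()` crosses a rate-ratio grid with a set of baseline truncations.
Each cell refits the baseline on the shortened record — so the power cost
of a short baseline includes the extra estimation uncertainty, not just
fewer months — then runs `n_sim` simulate-and-reestimate replicates
(default 500). Reported per cell: power, mean estimated rate ratio,
coverage of the truth, mean log-scale CI width, convergence counts, the
cell's $\hat\sigma$ and mean monthly count.

Seeding: a single `master_seed` spawns one seed per cell, each of which
spawns one seed per replicate, so results are bit-reproducible and
independent of execution order.

## The synthetic fixture generator

`generate_series()` draws ground-truth series from exactly the baseline
model's parameterization (same $t$ convention, same harmonic phases), so
correct-specification experiments are literal. Defaults mirror the
motivating setting — 84 months (seven pre-vaccine years), ~150 counts per
month, overdispersion SD 0.1, a dominant annual harmonic (log-amplitude
0.25 on the cosine with the sine at a third of that, fixing an arbitrary
but reproducible phase) and a weak 6-month harmonic (0.05). The amplitude
knobs map to cosine coefficients for simplicity; pass `beta` to set all six
coefficients directly. `brazil_like_panel()` spreads mean counts
log-uniformly over 30–1900 per month (the span observed across 27
state-level series) and $\sigma$ uniformly over 0.05–0.3, a range chosen
once so that power at a 20% decline traverses essentially its whole range;
it drives the qualitative power-versus-characteristics checks.

What the fixtures deliberately do not emulate: non-linear trends, abrupt
coding changes, epidemic years, autocorrelated residuals. Tests passing on
these fixtures therefore demonstrate internal correctness of the machinery
under correct specification — the tool's stated best-case framing — not
robustness to misspecification; with a strong non-linear trend the ITS
estimate can be badly biased regardless of power.

## Numerical and design choices

- Quadrature order 25 by default; doubling it changes fitted log-likelihoods
  by under $10^{-4}$ on fixture data (checked in the suite).
- Dates are normalized to month starts; gaps, duplicates and missing counts
  are hard errors (the likelihood assumes a complete monthly grid; silent
  imputation would corrupt the seasonality estimate).
- Date strings are ISO by default; day-first dialects require an explicit
  `date_format` — ambiguous orders are never guessed.
- MVN draws use an eigendecomposition square root, so the degenerate
  zero-covariance case returns the mean exactly; an indefinite covariance
  is an error with a jitter suggestion rather than a silent repair.
- Problem sizes in the shipped experiments — 500 replicates for centering,
  1,000 for type-I error and coverage, 200 per cell for the qualitative
  panel comparisons — balance Monte-Carlo error (binomial SE ~0.7% at
  1,000) against desk-scale runtimes of a few minutes.
- AR(1) random effects are intentionally out of scope: with a trend term
  they are weakly identified and can bias the trend and control
  coefficients, so independent observation-level effects are used
  throughout.

## Limitations

Power estimates here are *best-case*: the analysis model is exactly the
generating model, the introduction date is known, and all non-vaccine
structure is linear-plus-seasonal. Real evaluations face coding changes,
epidemics of other pathogens and non-linear trends, any of which can
dominate the statistical considerations quantified here. The rate-ratio
grid is restricted to declines ($\mathrm{IRR} \le 1$); non-monotone or
delayed effects are not modelled.
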