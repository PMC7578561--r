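# itspower

Simulation-based power calculations for interrupted time series (ITS)
evaluations of vaccine impact.

## The problem

After a vaccine is rolled out, its population-level effect is usually
estimated by comparing disease rates before and after introduction within a
single monthly time series. Whether such an analysis can detect a real
decline depends on features of the data that vary enormously between
settings: the number of cases per month, the strength of seasonality and
secular trends, the amount of unexplained month-to-month variability, and
how many years of pre-vaccine data exist. `itspower` answers the question
*"with the data I have, what is my chance of detecting a decline of a given
size?"* — by simulation, before any formal evaluation is attempted. It is
aimed at epidemiologists and biostatisticians planning vaccine impact
studies from routine surveillance or hospitalization counts.

## The model

Pre-vaccine monthly counts are fitted with a seasonal Poisson regression
carrying a Gaussian observation-level random intercept (a Poisson-lognormal
model):

```
Y_t  ~ Poisson(exp(mu_t + phi_t)),        phi_t ~ N(0, sigma^2)
mu_t = b0 + b1 t + b2 cos(2*pi*t/12) + b3 sin(2*pi*t/12)
             + b4 cos(2*pi*t/6)  + b5 sin(2*pi*t/6)  [+ control terms]
```

`sigma` is the *unexplained variability* — everything the trend, the
harmonics and any control series cannot account for. The marginal
likelihood (one Poisson-lognormal integral per month) is evaluated by
adaptive Gauss-Hermite quadrature and maximized directly.

Post-vaccine counts are then simulated from the fitted model: one draw of
the coefficients from `MVN(beta_hat, vcov)` per replicate, fresh `phi_t`
draws each month, and a known vaccine effect injected as a log-scale linear
ramp `v_t` falling from 0 to `log(IRR_final)` over a configurable number of
months (24 by default; 1 gives a step change). Each simulated series —
observed baseline plus simulated post period — is re-analysed with the same
model augmented by a linear spline starting at introduction, and the rate
ratio at the end of the ramp is `exp(ramp * beta_v)` with a Wald interval.
Power is the fraction of replicates whose 95% CI excludes 1; the engine
also reports bias, CI coverage of the true rate ratio and mean CI width,
across a grid of effect sizes and shortened baselines.

## Worked example

A small synthetic demonstration series (~460 pneumonia-like counts/month
for 8 years, with a non-respiratory control column) ships with the package:

```r
library(itspower)

series <- read_timeseries(
  system.file("extdata", "chile_like_synthetic.csv", package = "itspower"),
  date_col = "date", outcome_col = "outcome", control_cols = "control"
)
window <- analysis_window("2009-01", "2010-12", ramp_months = 24)

fit <- fit_baseline(split_periods(series, window)$pre, control_mode = "covariate")
glance(fit)
#>    sigma logLik  nobs    df converged
#> 1 0.0760  -369.    72     8 TRUE

result <- run_power(series, window,
                    power_config(irr_grid = c(0.7, 0.8, 0.9),
                                 n_sim = 200, master_seed = 42),
                    control_mode = "covariate")
tidy(result)
#>     irr baseline_drop power mean_irr coverage mean_ci_width n_converged n_failed
#> 1   0.7             0 1        0.701    0.945         0.200         200        0
#> 2   0.8             0 0.98     0.804    0.935         0.199         200        0
#> 3   0.9             0 0.555    0.896    0.95          0.198         200        0
```

Read: the 72-month baseline has unexplained SD 0.076 on the log scale.
With two evaluation years, a 30% decline (rate ratio 0.7) would essentially
always be detected, a 20% decline 98% of the time, and a 10% decline only
55% of the time; the mean estimate in each row sits on the injected truth,
and the 95% intervals cover it at roughly the nominal rate.

Plots: `plot_simulated_series(result)` (simulated-series spaghetti),
`plot_estimates(result)` (per-replicate rate ratios against the truth
line), `autoplot(result)` (power against unexplained variability or mean
counts). `summarize_report(result, "out/")` writes the CSVs and plots in
one call.

The same analysis runs from the shell:

```sh
exec/itspower run --input inst/extdata/chile_like_synthetic.csv \
  --date-col date --outcome-col outcome --control-cols control \
  --intro-date 2009-01 --eval-end 2010-12 --irr 0.7,0.8,0.9 \
  --nsim 200 --seed 42 --control-mode covariate --out out/
exec/itspower fixture --preset chile-like --out my_fixture.csv
```

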