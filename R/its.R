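#' Linear-spline vaccine term
#'
#' Zero before the introduction month, then months elapsed since
#' introduction (introduction month itself = 0), capped at `ramp_months`
#' where the effect stabilizes.
#'
#' @param dates Date vector of series months.
#' @param window an [analysis_window()].
#' @return numeric vector aligned to `dates`.
#' @export
spline_column <- function(dates, window) {
  stopifnot(inherits(window, "analysis_window"))
  m <- as.numeric(month_diff(floor_month(dates), window$intro_date))
  pmin(pmax(m, 0), window$ramp_months)
}

#' Rate ratio and Wald interval from the spline coefficient
#'
#' The log rate ratio at the end of the ramp is `ramp_months * beta_v`
#' (the spline coefficient is the log-rate change per ramp month), so
#' `irr = exp(ramp_months * beta_v)` with interval
#' `exp(ramp_months * (beta_v +/- z * se_v))`.
#'
#' @param beta_v spline coefficient (log scale, per month of ramp).
#' @param se_v its standard error (>= 0).
#' @param ramp_months ramp length in months.
#' @param alpha two-sided level (default 0.05 for a 95% interval).
#' @return tibble with `irr`, `ci_low`, `ci_high`.
#' @export
irr_from_coef <- function(beta_v, se_v, ramp_months = 24, alpha = 0.05) {
  assert_scalar_number(beta_v, "beta_v")
  assert_scalar_number(se_v, "se_v")
  if (se_v < 0) stop_its("`se_v` must be nonnegative.", "domain")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop_its("`alpha` must lie strictly inside (0, 1).", "domain")
  }
  z <- qnorm(1 - alpha / 2)
  tibble(
    irr = exp(ramp_months * beta_v),
    ci_low = exp(ramp_months * (beta_v - z * se_v)),
    ci_high = exp(ramp_months * (beta_v + z * se_v))
  )
}

#' Fit the interrupted-time-series model
#'
#' Fits the full series (baseline plus post period) with the same seasonal
#' Poisson-lognormal machinery as [fit_baseline()], augmented with a
#' linear-spline vaccine term starting at the introduction month and
#' stabilizing after `ramp_months`. The rate ratio at the end of the ramp
#' is `exp(ramp_months * beta_v)`; significance means the two-sided Wald
#' interval excludes 1.
#'
#' @param data a `monthly_series` or a `simulated_dataset`.
#' @param window an [analysis_window()].
#' @param control_mode how controls enter; see [build_design()].
#' @param quad_order Gauss-Hermite order.
#' @param alpha two-sided level for the Wald interval.
#' @return an `its_fit` with `beta_v`, `se_v`, `irr`, `ci_low`, `ci_high`,
#'   `significant`, `converged`, plus the underlying coefficient vector and
#'   covariance. `extrapolated` flags an evaluation period shorter than the
#'   ramp (the ramp-end rate ratio is then a slope extrapolation).
#' @export
fit_its <- function(data, window, control_mode = "none", quad_order = 25,
                    alpha = 0.05) {
  series <- if (inherits(data, "simulated_dataset")) data$series else data
  stopifnot(inherits(window, "analysis_window"))
  d <- series$date
  if (window$intro_date <= d[1L] || window$intro_date > d[length(d)]) {
    stop_its("Introduction month must fall inside the series with a nonempty baseline.", "range")
  }
  design <- build_design(series, control_mode)
  vax <- spline_column(series$date, window)
  X <- cbind(design$X, vaccine = vax)
  fit <- pln_fit(series$outcome, X, design$offset, quad_order = quad_order)

  beta_v <- unname(fit$beta["vaccine"])
  se_v <- sqrt(max(fit$vcov["vaccine", "vaccine"], 0))
  est <- irr_from_coef(beta_v, se_v, window$ramp_months, alpha)
  n_post_obs <- sum(d >= window$intro_date)
  structure(
    c(fit, list(
      beta_v = beta_v, se_v = se_v,
      irr = est$irr, ci_low = est$ci_low, ci_high = est$ci_high,
      significant = est$ci_high < 1 || est$ci_low > 1,
      alpha = alpha, ramp_months = window$ramp_months,
      extrapolated = (n_post_obs - 1L) < window$ramp_months,
      window = window, control_mode = control_mode
    )),
    class = "its_fit"
  )
}

#' @export
print.its_fit <- function(x, ...) {
  cat(sprintf(
    "<its_fit> IRR at ramp end (%d mo): %.3f [%.3f, %.3f]%s%s%s\n",
    x$ramp_months, x$irr, x$ci_low, x$ci_high,
    if (x$significant) " *" else "",
    if (x$extrapolated) " (extrapolated beyond observed post period)" else "",
    if (x$converged) "" else " (NOT converged)"
  ))
  invisible(x)
}

#' Tidy an ITS fit
#'
#' @param x an `its_fit`.
#' @param ... unused.
#' @return tibble of coefficients (`term`, `estimate`, `std.error`).
#' @method tidy its_fit
#' @export
tidy.its_fit <- function(x, ...) {
  tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = sqrt(pmax(diag(x$vcov), 0))
  )
}

#' One-row summary of an ITS fit
#'
#' @param x an `its_fit`.
#' @param ... unused.
#' @return tibble with the rate-ratio estimate, Wald interval, significance
#'   and convergence.
#' @method glance its_fit
#' @export
glance.its_fit <- function(x, ...) {
  tibble(
    irr = x$irr, ci_low = x$ci_low, ci_high = x$ci_high,
    significant = x$significant, sigma = x$sigma,
    logLik = x$loglik, converged = x$converged,
    extrapolated = x$extrapolated
  )
}
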