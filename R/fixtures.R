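# Ground-truth generators. The fixture mean uses exactly the baseline-model
# design (same 0-based time index, same harmonic phases), so
# correct-specification tests are literal: data generated here satisfy the
# fitted model's assumptions by construction.

#' Specify a synthetic monthly-count fixture
#'
#' Defines a seasonal Poisson-lognormal generating process with known
#' coefficients: log-rate = `log(base_mean) + trend * t + amp12 * cos12 +
#' (amp12/3) * sin12 + amp6 * cos6 + (amp6/3) * sin6` plus a monthly
#' `N(0, sigma^2)` perturbation. The sin terms at a third of the cos
#' amplitude fix an (arbitrary but reproducible) seasonal phase; pass
#' `beta` to control all six coefficients directly.
#'
#' @param n_months series length (>= 12).
#' @param base_mean expected counts per month at `t = 0` ignoring
#'   seasonality (> 0).
#' @param trend log-scale slope per month.
#' @param amp12,amp6 log-scale amplitudes of the 12- and 6-month harmonics.
#' @param sigma overdispersion SD (>= 0).
#' @param beta optional length-6 coefficient vector overriding the above
#'   (intercept, time, cos12, sin12, cos6, sin6).
#' @param control optional list `list(base_mean =, shared_trend = TRUE)`
#'   describing a control series generated alongside the outcome.
#' @param start first month of the series.
#' @param label identifier.
#' @return a `fixture_spec` object.
#' @export
fixture_spec <- function(n_months = 84, base_mean = 150, trend = 0,
                         amp12 = 0.25, amp6 = 0.05, sigma = 0.1,
                         beta = NULL, control = NULL,
                         start = as.Date("2003-01-01"), label = "fixture") {
  if (!is.numeric(n_months) || n_months < 12) {
    stop_its("`n_months` must be at least 12.", "domain")
  }
  if (base_mean <= 0) stop_its("`base_mean` must be positive.", "domain")
  if (sigma < 0) stop_its("`sigma` must be nonnegative.", "domain")
  if (is.null(beta)) {
    beta <- c(log(base_mean), trend, amp12, amp12 / 3, amp6, amp6 / 3)
  }
  if (length(beta) != 6L) stop_its("`beta` must have 6 elements.", "domain")
  names(beta) <- c("intercept", "time", "cos12", "sin12", "cos6", "sin6")
  if (exp(max(abs(beta[1]) + abs(beta[2]) * n_months + sum(abs(beta[3:6])) + 6 * sigma)) > 1e9) {
    stop_its("Fixture mean would overflow the Poisson sampler.", "domain")
  }
  structure(
    list(n_months = as.integer(n_months), beta = beta, sigma = sigma,
         control = control, start = floor_month(start), label = label),
    class = "fixture_spec"
  )
}

fixture_mu <- function(spec, t) {
  theta <- 2 * pi * t
  X <- cbind(1, t, cos(theta / 12), sin(theta / 12), cos(theta / 6), sin(theta / 6))
  drop(X %*% spec$beta)
}

#' Generate a synthetic monthly series with known truth
#'
#' Counts are drawn as `Poisson(exp(mu_t + phi_t))` with `mu_t` from the
#' spec's coefficients and `phi_t ~ N(0, sigma^2)`. The generating
#' parameters travel with the series (attribute `truth`) so recovery tests
#' can compare estimates against them.
#'
#' @param spec a [fixture_spec()].
#' @return a `monthly_series`; `attr(, "truth")` holds `beta` and `sigma`.
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  t <- seq_len(spec$n_months) - 1
  mu <- fixture_mu(spec, t)
  phi <- rnorm(spec$n_months, 0, spec$sigma)
  y <- rpois(spec$n_months, exp(mu + phi))
  controls <- NULL
  if (!is.null(spec$control)) {
    cb <- spec$beta
    cb[1] <- log(spec$control$base_mean)
    if (!isTRUE(spec$control$shared_trend)) cb[2] <- 0
    cmu <- drop(cbind(1, t, cos(2 * pi * t / 12), sin(2 * pi * t / 12),
                      cos(2 * pi * t / 6), sin(2 * pi * t / 6)) %*% cb)
    cphi <- rnorm(spec$n_months, 0, spec$sigma)
    controls <- list(control = rpois(spec$n_months, exp(cmu + cphi)))
  }
  out <- monthly_series(month_seq(spec$start, spec$n_months), y,
                        controls = controls, label = spec$label)
  attr(out, "truth") <- list(beta = spec$beta, sigma = spec$sigma)
  out
}

#' Panel of fixtures spanning count and noise ranges
#'
#' Emulates a multi-state panel: mean monthly counts log-uniform over
#' `count_range`, overdispersion SD uniform over `sigma_range` — the input
#' for studying how power varies with series characteristics.
#'
#' @param n_series number of series (27 mirrors 26 states plus a federal
#'   district).
#' @param count_range length-2 positive range of mean monthly counts.
#' @param sigma_range length-2 nonnegative range of overdispersion SDs.
#' @param n_months months per series.
#' @param seed optional seed applied before generation.
#' @return list of `monthly_series`, each carrying its `truth` attribute.
#' @export
brazil_like_panel <- function(n_series = 27, count_range = c(30, 1900),
                              sigma_range = c(0.05, 0.3), n_months = 84,
                              seed = NULL) {
  if (any(count_range <= 0)) stop_its("`count_range` must be positive.", "domain")
  if (any(sigma_range < 0)) stop_its("`sigma_range` must be nonnegative.", "domain")
  if (!is.null(seed)) set.seed(seed)
  means <- exp(runif(n_series, log(count_range[1]), log(count_range[2])))
  sigmas <- runif(n_series, sigma_range[1], sigma_range[2])
  purrr::map(seq_len(n_series), function(i) {
    generate_series(fixture_spec(
      n_months = n_months, base_mean = means[i], sigma = sigmas[i],
      label = sprintf("panel-%02d", i)
    ))
  })
}
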