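#' Fit the seasonal Poisson-lognormal baseline model
#'
#' Fits monthly counts from the pre-vaccine period with a Poisson regression
#' on a linear time trend and 12- and 6-month harmonics, plus a Gaussian
#' observation-level random intercept capturing overdispersion. Estimation
#' is maximum likelihood: the marginal Poisson-lognormal likelihood is
#' evaluated by Gauss-Hermite quadrature and maximized jointly over the
#' coefficients and `log(sigma)`.
#'
#' @param series a `monthly_series` (the pre-vaccine baseline; >= 12 months).
#' @param control_mode how control series enter the model; see
#'   [build_design()].
#' @param quad_order Gauss-Hermite order (default 25).
#' @param sigma_init starting value for the random-intercept SD.
#' @return a `baseline_fit`: coefficients `beta`, their Wald covariance
#'   `vcov`, overdispersion SD `sigma`, `loglik`, a `converged` flag, and the
#'   `design` used.
#' @seealso [unexplained_sd()], [simulate_post()], [tidy.baseline_fit()]
#' @export
fit_baseline <- function(series, control_mode = "none", quad_order = 25,
                         sigma_init = 0.1) {
  if (nrow(series) < 12L) {
    stop_its("Baseline must span at least 12 months (one seasonal cycle).", "range")
  }
  if (all(series$outcome == 0)) {
    stop_its("Outcome is all zero; the baseline model is degenerate.", "degenerate")
  }
  design <- build_design(series, control_mode)
  fit <- pln_fit(series$outcome, design$X, design$offset,
                 quad_order = quad_order, sigma_init = sigma_init)
  structure(
    c(fit, list(design = design, series = series, control_mode = control_mode,
                quad_order = quad_order)),
    class = "baseline_fit"
  )
}

#' Unexplained variability of a fitted baseline
#'
#' Returns the estimated SD of the observation-level random intercept — the
#' operational measure of unexplained variability that power is summarized
#' against.
#'
#' @param fit a converged `baseline_fit`.
#' @return the SD (log-rate scale).
#' @export
unexplained_sd <- function(fit) {
  stopifnot(inherits(fit, "baseline_fit"))
  if (!isTRUE(fit$converged)) {
    stop_its("Baseline fit did not converge; unexplained SD is unreliable.", "state")
  }
  fit$sigma
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf(
    "<baseline_fit> %d months, %d coefficients, sigma = %.4f, logLik = %.2f%s\n",
    nrow(x$series), length(x$beta), x$sigma, x$loglik,
    if (x$converged) "" else " (NOT converged)"
  ))
  print(tidy(x))
  invisible(x)
}

#' Tidy a baseline fit
#'
#' @param x a `baseline_fit`.
#' @param ... unused.
#' @return a tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`.
#' @method tidy baseline_fit
#' @export
tidy.baseline_fit <- function(x, ...) {
  tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = sqrt(pmax(diag(x$vcov), 0))
  )
}

#' One-row summary of a baseline fit
#'
#' @param x a `baseline_fit`.
#' @param ... unused.
#' @return a tibble with `sigma`, `logLik`, `nobs`, `df`, `converged`.
#' @method glance baseline_fit
#' @export
glance.baseline_fit <- function(x, ...) {
  tibble(
    sigma = x$sigma,
    logLik = x$loglik,
    nobs = nrow(x$series),
    df = length(x$beta) + 1L,
    converged = x$converged
  )
}

#' Serialize a baseline fit summary to JSON
#'
#' Captures everything needed to re-simulate exactly: coefficients,
#' standard errors, the full covariance matrix, sigma, log-likelihood,
#' convergence and column names.
#'
#' @param fit a `baseline_fit`.
#' @param path optional file path; when given the JSON is written there.
#' @return the JSON string, invisibly when `path` is given.
#' @export
fit_summary_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "baseline_fit"))
  payload <- list(
    coefficients = as.list(fit$beta),
    std_errors = as.list(stats::setNames(sqrt(pmax(diag(fit$vcov), 0)), names(fit$beta))),
    vcov = unname(fit$vcov),
    sigma = fit$sigma,
    loglik = fit$loglik,
    converged = fit$converged,
    control_mode = fit$control_mode,
    quad_order = fit$quad_order,
    columns = names(fit$beta),
    origin = format(fit$design$origin, "%Y-%m-%d")
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
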