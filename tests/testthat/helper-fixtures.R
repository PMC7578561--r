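# Shared helpers: small builders and the adaptive-quadrature likelihood
# oracle the Gauss-Hermite implementation is checked against.

months_from <- function(start, n) {
  seq(as.Date(paste0(start, "-01")), by = "month", length.out = n)
}

make_series <- function(counts, start = "2003-01", controls = NULL, ...) {
  monthly_series(months_from(start, length(counts)), counts,
                 controls = controls, ...)
}

# Independent oracle: one-dimensional Poisson-lognormal log-likelihood per
# observation by adaptive numeric integration on a stabilized scale. The
# integrand can peak far from zero (the count can pull the posterior of phi
# many prior SDs out), so the window is centred on the peak found by a
# direct search and sized by the local curvature.
pln_loglik_adaptive <- function(y, mu, sigma) {
  if (sigma == 0) return(sum(dpois(y, exp(mu), log = TRUE)))
  sum(vapply(seq_along(y), function(i) {
    lp <- function(phi) dpois(y[i], exp(mu[i] + phi), log = TRUE) +
      dnorm(phi, 0, sigma, log = TRUE)
    opt <- optimize(lp, c(-80, 80), maximum = TRUE, tol = 1e-10)
    m <- opt$objective
    width <- 1 / sqrt(exp(mu[i] + opt$maximum) + 1 / sigma^2)
    val <- integrate(function(phi) exp(lp(phi) - m),
                     lower = opt$maximum - 40 * width,
                     upper = opt$maximum + 40 * width,
                     rel.tol = 1e-11, abs.tol = 0)$value
    m + log(val)
  }, numeric(1)))
}

# Writes a monthly series to a temp CSV and returns the path.
write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(df, path)
  path
}

# A fake converged baseline fit for operations that only need
# (beta, vcov, sigma, converged).
fake_fit <- function(beta, vcov, sigma = 0) {
  structure(list(beta = beta, vcov = vcov, sigma = sigma, converged = TRUE),
            class = "baseline_fit")
}
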