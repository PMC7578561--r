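# Poisson-lognormal marginal likelihood.
#
# Each count contributes log integral Pois(y | exp(eta + phi)) N(phi; 0, s^2) dphi.
# With an observation-level random intercept the likelihood factorizes into
# one-dimensional integrals, so fixed-order Gauss-Hermite quadrature is cheap
# and accurate:
#   integral f(phi) N(phi; 0, s^2) dphi ~= sum_k (w_k / sqrt(pi)) f(sqrt(2) s x_k)
# All sums are done on the log scale (log-sum-exp) for stability.

gh_cache <- new.env(parent = emptyenv())

gh_rule <- function(order) {
  key <- as.character(order)
  if (is.null(gh_cache[[key]])) {
    gh_cache[[key]] <- pracma::gaussHermite(order)
  }
  gh_cache[[key]]
}

#' Marginal log-likelihood of the Poisson-lognormal model
#'
#' Computes `sum_t log integral Pois(y_t | exp(eta_t + phi)) N(phi; 0, sigma^2) dphi`
#' by fixed-order adaptive Gauss-Hermite quadrature (the rule is recentred
#' and rescaled at each observation's posterior mode), where
#' `eta = X beta + offset`. At `sigma = 0` this is exactly the plain
#' Poisson log-likelihood.
#'
#' @param beta coefficient vector matching the design columns.
#' @param sigma standard deviation (>= 0) of the observation-level random
#'   intercept.
#' @param y nonnegative integer counts.
#' @param design a `design_matrix` from [build_design()], or a plain numeric
#'   model matrix.
#' @param quad_order number of quadrature nodes (default 25).
#' @return the marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(beta, sigma, y, design, quad_order = 25) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    stop_its("`sigma` must be a single nonnegative number.", "domain")
  }
  if (!is_count_vector(y)) {
    stop_its("`y` must be nonnegative integer counts.", "domain")
  }
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  offset <- if (inherits(design, "design_matrix")) design$offset else rep(0, nrow(X))
  eta <- drop(X %*% beta) + offset
  pln_loglik(y, eta, sigma, quad_order)$value
}

# Log-likelihood and, on request, the gradient pieces shared by the fitter.
#
# The quadrature is adaptive: the fixed-order rule is recentred at each
# observation's posterior mode of phi and rescaled by the local curvature,
# so accuracy is uniform even when the count pulls the integrand far from
# the prior mode (large y with small exp(eta), and vice versa). Gradients
# come from Fisher's identity — posterior expectations of the complete-data
# score — evaluated with the same nodes and weights.
pln_loglik <- function(y, eta, sigma, quad_order, gradient = FALSE) {
  if (sigma < 1e-8) {
    ll <- y * eta - exp(eta) - lgamma(y + 1)
    out <- list(value = sum(ll))
    if (gradient) {
      out$g_eta <- y - exp(eta)
      out$g_logsigma <- 0
    }
    return(out)
  }
  gh <- gh_rule(quad_order)
  n <- length(y)
  inv_s2 <- 1 / sigma^2

  # Newton iterations for the posterior mode of phi (strictly concave in phi)
  phi <- rep(0, n)
  for (it in 1:100) {
    lam <- exp(pmin(eta + phi, 700))
    step <- (y - lam - phi * inv_s2) / (lam + inv_s2)
    phi <- phi + step
    if (max(abs(step)) < 1e-12) break
  }
  h <- exp(pmin(eta + phi, 700)) + inv_s2   # negative curvature at the mode
  scale <- sqrt(2 / h)

  phik <- phi + outer(scale, gh$x)          # n x k node positions
  a <- eta + phik
  logint <- y * a - exp(a) - lgamma(y + 1) -
    0.5 * phik^2 * inv_s2 - log(sigma) - 0.5 * log(2 * pi)
  M <- sweep(logint, 2, log(gh$w) + gh$x^2, "+")
  m <- as.numeric(do.call(pmax, c(asplit(M, 2), list(na.rm = TRUE))))
  m[!is.finite(m)] <- 0                     # all-(-Inf) rows would otherwise NaN
  S <- m + log(rowSums(exp(M - m)))
  out <- list(value = sum(S + log(scale)))
  if (gradient) {
    P <- exp(M - S)                         # normalized node weights per row
    out$g_eta <- rowSums(P * (y - exp(a)))
    out$g_logsigma <- sum(P * (phik^2 * inv_s2 - 1))
  }
  out
}

# Maximum-likelihood fit over (beta, log sigma) with analytic gradients.
# Init: beta at the plain Poisson GLM solution, log sigma at log(0.1).
pln_fit <- function(y, X, offset = NULL, quad_order = 25, sigma_init = 0.1) {
  n <- length(y)
  p <- ncol(X)
  offset <- offset %||% rep(0, n)
  init <- tryCatch(
    suppressWarnings(
      glm.fit(X, y, family = poisson(), offset = offset)$coefficients
    ),
    error = function(e) NULL
  )
  if (is.null(init) || anyNA(init)) {
    init <- c(log(mean(y) + 0.5) - mean(offset), rep(0, p - 1L))
  }
  par0 <- c(init, log(sigma_init))

  # L-BFGS-B asks for fn and gr at the same point back to back; evaluate the
  # likelihood once per point and serve both from a one-slot cache.
  last <- list(par = NULL, value = NULL, grad = NULL)
  evaluate <- function(par) {
    if (!identical(par, last$par)) {
      eta <- drop(X %*% par[seq_len(p)]) + offset
      g <- pln_loglik(y, eta, exp(par[p + 1L]), quad_order, gradient = TRUE)
      v <- -g$value
      gr <- -c(drop(crossprod(X, g$g_eta)), g$g_logsigma)
      gr[!is.finite(gr)] <- 0
      last <<- list(par = par,
                    value = if (is.finite(v)) v else 1e10,
                    grad = gr)
    }
    last
  }
  negll <- function(par) evaluate(par)$value
  neggr <- function(par) evaluate(par)$grad

  opt <- tryCatch(
    optim(par0, negll, neggr, method = "L-BFGS-B",
          lower = c(rep(-Inf, p), -10), upper = c(rep(Inf, p), 3),
          control = list(maxit = 500, factr = 1e8)),
    error = function(e) NULL
  )
  if (is.null(opt)) {
    # rare line-search pathologies; retry gradient-free from the same start
    opt <- tryCatch(
      optim(par0, function(q) negll(c(q[seq_len(p)], min(max(q[p + 1L], -10), 3))),
            method = "Nelder-Mead", control = list(maxit = 5000)),
      error = function(e) NULL
    )
    if (!is.null(opt)) opt$par[p + 1L] <- min(max(opt$par[p + 1L], -10), 3)
  }
  if (is.null(opt)) {
    stop_its("Likelihood optimization failed (non-finite objective).", "optimization")
  }
  beta <- unname(opt$par[seq_len(p)])
  sigma <- unname(exp(opt$par[p + 1L]))
  names(beta) <- colnames(X)

  # Wald vcov for beta: inverse observed information at the optimum,
  # conditional on sigma-hat (matches standard mixed-model Wald output).
  negll_beta <- function(b) negll(c(b, opt$par[p + 1L]))
  neggr_beta <- function(b) neggr(c(b, opt$par[p + 1L]))[seq_len(p)]
  H <- tryCatch(optimHess(beta, negll_beta, neggr_beta), error = function(e) NULL)
  vcov <- NULL
  if (!is.null(H)) {
    H <- (H + t(H)) / 2
    vcov <- tryCatch(solve(H), error = function(e) NULL)
  }
  converged <- opt$convergence == 0 && !is.null(vcov) &&
    all(is.finite(vcov)) && all(diag(vcov) >= 0)
  if (is.null(vcov)) vcov <- matrix(NA_real_, p, p)
  dimnames(vcov) <- list(colnames(X), colnames(X))

  list(
    beta = beta, sigma = sigma, vcov = vcov,
    loglik = -opt$value, converged = converged,
    optim = list(convergence = opt$convergence, message = opt$message,
                 counts = opt$counts)
  )
}
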