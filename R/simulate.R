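#' Specify a vaccine effect
#'
#' The effect is a log-scale linear ramp: 0 in the introduction month,
#' declining linearly to `log(irr_final)` at `ramp_months`, constant after.
#' `ramp_months = 1` gives a step change.
#'
#' @param irr_final rate ratio at the end of the ramp, in (0, 1].
#' @param ramp_months positive integer ramp length (default 24).
#' @return a `vaccine_effect` object.
#' @export
vaccine_effect <- function(irr_final, ramp_months = 24) {
  assert_scalar_number(irr_final, "irr_final")
  if (irr_final <= 0 || irr_final > 1) {
    stop_its("`irr_final` must lie in (0, 1].", "domain")
  }
  if (!is.numeric(ramp_months) || ramp_months < 1) {
    stop_its("`ramp_months` must be a positive integer.", "domain")
  }
  structure(list(irr_final = irr_final, ramp_months = as.integer(ramp_months)),
            class = "vaccine_effect")
}

#' Log-scale vaccine ramp vector
#'
#' @param n_post number of post-introduction months (month 0 is the
#'   introduction month itself).
#' @param effect a [vaccine_effect()].
#' @return numeric vector of length `n_post`: `v_t = min(t, ramp)/ramp *
#'   log(irr_final)`.
#' @export
vaccine_ramp <- function(n_post, effect) {
  stopifnot(inherits(effect, "vaccine_effect"))
  if (!is.numeric(n_post) || n_post < 1) {
    stop_its("`n_post` must be >= 1.", "domain")
  }
  t <- seq_len(n_post) - 1
  pmin(t, effect$ramp_months) / effect$ramp_months * log(effect$irr_final)
}

#' Draw regression coefficients from their sampling distribution
#'
#' One multivariate-normal draw (per simulated series) from
#' `MVN(beta, vcov)` of a fitted baseline, propagating parameter
#' uncertainty into the simulations.
#'
#' @param fit a converged `baseline_fit`.
#' @param n number of draws.
#' @return for `n = 1` a named vector; otherwise an `n` x p matrix.
#' @export
draw_parameters <- function(fit, n = 1) {
  stopifnot(inherits(fit, "baseline_fit"))
  if (!isTRUE(fit$converged)) {
    stop_its("Cannot draw parameters from a non-converged fit.", "state")
  }
  V <- (fit$vcov + t(fit$vcov)) / 2
  p <- length(fit$beta)
  if (all(V == 0)) {
    draws <- matrix(rep(fit$beta, each = n), n, p)
  } else {
    e <- eigen(V, symmetric = TRUE)
    if (any(e$values < -1e-8 * max(abs(e$values), 1))) {
      stop_its("Coefficient covariance is not positive semi-definite; consider adding a small diagonal jitter.", "numerical")
    }
    L <- e$vectors %*% (t(e$vectors) * sqrt(pmax(e$values, 0)))
    z <- matrix(rnorm(n * p), n, p)
    draws <- z %*% L + matrix(rep(fit$beta, each = n), n, p)
  }
  colnames(draws) <- names(fit$beta)
  if (n == 1) drop(draws) else draws
}

#' Simulate post-vaccine counts from a fitted baseline
#'
#' For each post month: `mu_t` from a single fresh coefficient draw and the
#' post-period design; an independent `phi_t ~ N(0, sigma^2)`; and a count
#' `Y_t ~ Poisson(exp(mu_t + phi_t + v_t))` where `v_t` is the vaccine ramp.
#' One coefficient draw per replicate; `phi` is drawn per month.
#'
#' @param fit a converged `baseline_fit`.
#' @param post_design a `design_matrix` for the post months, built with
#'   `origin` at the baseline start so time index and harmonic phase
#'   continue the baseline numbering.
#' @param effect a [vaccine_effect()].
#' @param beta_draw optional fixed coefficient vector (skips the MVN draw).
#' @return integer vector of simulated counts.
#' @export
simulate_post <- function(fit, post_design, effect, beta_draw = NULL) {
  stopifnot(inherits(fit, "baseline_fit"), inherits(post_design, "design_matrix"))
  if (is.null(beta_draw)) beta_draw <- draw_parameters(fit)
  n <- nrow(post_design$X)
  mu <- drop(post_design$X %*% beta_draw) + post_design$offset
  phi <- rnorm(n, 0, fit$sigma)
  lambda <- exp(mu + phi + vaccine_ramp(n, effect))
  bad <- which(!is.finite(lambda) | lambda > 1e9)
  if (length(bad)) {
    stop_its(
      sprintf("Simulated rate overflows at month %s.",
              format(post_design$dates[bad[1]], "%Y-%m")),
      "simulation"
    )
  }
  rpois(n, lambda)
}

#' Combine observed baseline with simulated post-period counts
#'
#' @param pre the observed pre-vaccine `monthly_series` (carried through
#'   bit-identically; power calculations are conditional on it).
#' @param post_counts simulated counts for the months directly following
#'   `pre`.
#' @param controls_post optional tibble with a `date` column and one column
#'   per control, covering exactly the post months (must abut `pre` with no
#'   gap or overlap).
#' @param truth the [vaccine_effect()] injected, if any.
#' @param replicate_id integer replicate index.
#' @param beta_draw the coefficient vector used for this replicate.
#' @return a `simulated_dataset`: list with the combined `series`, `truth`,
#'   `replicate_id` and `beta_draw`.
#' @export
assemble <- function(pre, post_counts, controls_post = NULL, truth = NULL,
                     replicate_id = NA_integer_, beta_draw = NULL) {
  n_post <- length(post_counts)
  post_dates <- month_seq(seq(pre$date[nrow(pre)], by = "month", length.out = 2)[2], n_post)
  ctrl <- series_controls(pre)
  post <- tibble(date = post_dates, outcome = as.numeric(post_counts))
  if (length(ctrl)) {
    if (is.null(controls_post)) {
      stop_its("Baseline has controls; supply `controls_post` for the post months.", "config")
    }
    if (!identical(floor_month(controls_post$date), post_dates)) {
      stop_its("`controls_post` dates must exactly abut the baseline (no gap or overlap).", "contiguity")
    }
    for (nm in ctrl) post[[nm]] <- as.numeric(controls_post[[nm]])
  }
  full <- dplyr::bind_rows(as_tibble(pre), post)
  series <- restore_series(full, pre)
  structure(
    list(series = series, truth = truth, replicate_id = replicate_id,
         beta_draw = beta_draw, n_pre = nrow(pre)),
    class = "simulated_dataset"
  )
}

#' Extend control series into the simulated post period
#'
#' The simulation needs post-period values for any control; absent
#' user-supplied ones, each control's seasonal profile (mean count per
#' calendar month over the last three baseline years, rounded) is repeated
#' forward.
#'
#' @param pre baseline `monthly_series` with controls.
#' @param n_post number of post months.
#' @return tibble with `date` and one column per control.
#' @export
extend_controls <- function(pre, n_post) {
  ctrl <- series_controls(pre)
  post_dates <- month_seq(seq(pre$date[nrow(pre)], by = "month", length.out = 2)[2], n_post)
  out <- tibble(date = post_dates)
  recent <- utils::tail(as_tibble(pre), 36L)
  mon <- as.integer(format(recent$date, "%m"))
  for (nm in ctrl) {
    prof <- tapply(recent[[nm]], mon, mean)
    out[[nm]] <- as.numeric(round(prof[as.character(as.integer(format(post_dates, "%m")))]))
  }
  out
}

#' Export simulated replicates as a long table
#'
#' @param datasets list of `simulated_dataset` objects.
#' @param path optional CSV path.
#' @return long tibble (`replicate`, `date`, `count`, `period`).
#' @export
replicates_long <- function(datasets, path = NULL) {
  out <- purrr::map_dfr(datasets, function(d) {
    tibble(
      replicate = d$replicate_id,
      date = d$series$date,
      count = d$series$outcome,
      period = rep(c("pre", "post"), c(d$n_pre, nrow(d$series) - d$n_pre))
    )
  })
  if (!is.null(path)) readr::write_csv(out, path)
  out
}
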