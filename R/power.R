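#' Configure a power experiment
#'
#' @param irr_grid rate ratios in (0, 1] to simulate (1 gives the null).
#' @param n_sim replicates per cell (default 500).
#' @param alpha two-sided level defining significance (default 0.05).
#' @param baseline_drops years of baseline to drop, one cell per value
#'   (default 0 = full baseline).
#' @param master_seed integer seed; the full experiment is deterministic
#'   given it. Each replicate uses an independent child seed so results do
#'   not depend on execution order.
#' @param ramp_months ramp length for the injected and estimated effect.
#' @param keep_series how many replicates per cell to retain as full
#'   simulated series (for the spaghetti plot).
#' @return a `power_config` object.
#' @export
power_config <- function(irr_grid = 0.8, n_sim = 500, alpha = 0.05,
                         baseline_drops = 0, master_seed = 1,
                         ramp_months = 24, keep_series = 30) {
  if (any(irr_grid <= 0 | irr_grid > 1)) {
    stop_its("Every rate ratio in `irr_grid` must lie in (0, 1].", "domain")
  }
  if (n_sim < 1) stop_its("`n_sim` must be >= 1.", "domain")
  if (n_sim > 10000) {
    warn(sprintf("n_sim = %d is very large; runtimes grow linearly.", n_sim))
  }
  if (alpha <= 0 || alpha >= 1) stop_its("`alpha` must lie in (0, 1).", "domain")
  structure(
    list(irr_grid = irr_grid, n_sim = as.integer(n_sim), alpha = alpha,
         baseline_drops = as.integer(baseline_drops),
         master_seed = as.integer(master_seed),
         ramp_months = as.integer(ramp_months),
         keep_series = as.integer(keep_series)),
    class = "power_config"
  )
}

#' Run the simulation-based power calculation
#'
#' For each cell (rate ratio x baseline drop): truncate the baseline, fit
#' the seasonal Poisson-lognormal model, simulate `n_sim` post-vaccine
#' series with the specified effect injected (each from a fresh coefficient
#' draw, conditional on the observed baseline), refit the spline ITS model,
#' and aggregate. Power is the share of converged replicates whose Wald
#' interval excludes 1; coverage is the share containing the true rate
#' ratio. Non-converged replicates are excluded from the denominator and
#' counted in `n_failed`.
#'
#' @param series the observed `monthly_series` (baseline, possibly plus
#'   post months which are ignored for simulation).
#' @param window an [analysis_window()]; its `ramp_months` is overridden by
#'   the config's.
#' @param config a [power_config()].
#' @param control_mode how controls enter the models; see [build_design()].
#' @return a `power_result`: tibble with one row per cell (`irr`,
#'   `baseline_drop`, `power`, `mean_irr`, `coverage`, `mean_ci_width`,
#'   `n_converged`, `n_failed`, `unexplained_sd`, `mean_count`), with the
#'   per-replicate table in `attr(, "replicates")` and retained simulated
#'   series in `attr(, "series_sample")`.
#' @export
run_power <- function(series, window, config = power_config(),
                      control_mode = "none") {
  stopifnot(inherits(window, "analysis_window"), inherits(config, "power_config"))
  window <- analysis_window(window$intro_date, window$eval_end, config$ramp_months)
  pre_full <- split_periods(series, window)$pre
  n_post <- as.integer(month_diff(window$eval_end, window$intro_date)) + 1L

  cells <- tidyr::expand_grid(baseline_drop = config$baseline_drops,
                              irr = config$irr_grid)
  set.seed(config$master_seed)
  cell_seeds <- sample.int(.Machine$integer.max, nrow(cells))

  replicates <- vector("list", nrow(cells))
  kept <- vector("list", nrow(cells))
  summaries <- vector("list", nrow(cells))

  for (ci in seq_len(nrow(cells))) {
    drop_yrs <- cells$baseline_drop[ci]
    irr <- cells$irr[ci]
    base <- truncate_baseline(pre_full, drop_yrs)
    if (nrow(base) < 12L) {
      stop_its("A baseline drop leaves fewer than 12 months.", "range")
    }
    fit <- fit_baseline(base, control_mode)
    if (!fit$converged) {
      summaries[[ci]] <- tibble(
        irr = irr, baseline_drop = drop_yrs, power = NA_real_,
        mean_irr = NA_real_, coverage = NA_real_, mean_ci_width = NA_real_,
        n_converged = 0L, n_failed = config$n_sim,
        unexplained_sd = NA_real_, mean_count = mean(base$outcome)
      )
      next
    }
    effect <- vaccine_effect(irr, config$ramp_months)
    post_dates <- month_seq(window$intro_date, n_post)
    ctrl_post <- if (length(series_controls(base))) extend_controls(base, n_post) else NULL
    post_frame <- monthly_series(
      post_dates, rep(0, n_post),
      controls = if (is.null(ctrl_post)) NULL else as.list(ctrl_post[series_controls(base)])
    )
    post_design <- build_design(post_frame, control_mode, origin = base$date[1L])

    set.seed(cell_seeds[ci])
    rep_seeds <- sample.int(.Machine$integer.max, config$n_sim)

    rows <- vector("list", config$n_sim)
    keep <- vector("list", min(config$keep_series, config$n_sim))
    for (r in seq_len(config$n_sim)) {
      set.seed(rep_seeds[r])
      bd <- draw_parameters(fit)
      y_post <- simulate_post(fit, post_design, effect, beta_draw = bd)
      sim <- assemble(base, y_post, controls_post = ctrl_post,
                      truth = effect, replicate_id = r, beta_draw = bd)
      est <- fit_its(sim, window, control_mode, quad_order = fit$quad_order,
                     alpha = config$alpha)
      rows[[r]] <- tibble(
        irr_true = irr, baseline_drop = drop_yrs, replicate = r,
        irr = est$irr, ci_low = est$ci_low, ci_high = est$ci_high,
        significant = est$significant, converged = est$converged
      )
      if (r <= length(keep)) {
        keep[[r]] <- tibble(irr_true = irr, baseline_drop = drop_yrs,
                            replicate = r, date = sim$series$date,
                            count = sim$series$outcome)
      }
    }
    reps <- dplyr::bind_rows(rows)
    replicates[[ci]] <- reps
    kept[[ci]] <- dplyr::bind_rows(keep)
    ok <- reps[reps$converged, , drop = FALSE]
    summaries[[ci]] <- tibble(
      irr = irr, baseline_drop = drop_yrs,
      power = mean(ok$significant),
      mean_irr = mean(ok$irr),
      coverage = mean(ok$ci_low <= irr & irr <= ok$ci_high),
      mean_ci_width = mean(log(ok$ci_high) - log(ok$ci_low)),
      n_converged = nrow(ok), n_failed = config$n_sim - nrow(ok),
      unexplained_sd = unexplained_sd(fit),
      mean_count = mean(base$outcome)
    )
  }

  structure(
    dplyr::bind_rows(summaries),
    replicates = dplyr::bind_rows(replicates),
    series_sample = dplyr::bind_rows(kept),
    config = config, window = window,
    class = c("power_result", class(tibble()))
  )
}

#' Power across shortened baselines
#'
#' Convenience wrapper running [run_power()] over a set of baseline drops,
#' refitting the baseline model on each shortened record (so the loss of
#' estimation precision from fewer data is included).
#'
#' @inheritParams run_power
#' @param baseline_drops years to drop (default 0:3).
#' @return a `power_result` with one cell per (rate ratio, drop).
#' @export
power_vs_baseline_length <- function(series, window, config = power_config(),
                                     baseline_drops = 0:3,
                                     control_mode = "none") {
  config$baseline_drops <- as.integer(baseline_drops)
  run_power(series, window, config, control_mode)
}

#' Per-replicate estimates of a power result
#'
#' @param result a `power_result`.
#' @return tibble (`irr_true`, `baseline_drop`, `replicate`, `irr`,
#'   `ci_low`, `ci_high`, `significant`, `converged`).
#' @export
power_replicates <- function(result) {
  attr(result, "replicates")
}

#' Tidy a power result
#'
#' @param x a `power_result`.
#' @param ... unused.
#' @return the per-cell summary tibble.
#' @method tidy power_result
#' @export
tidy.power_result <- function(x, ...) {
  as_tibble(x)
}

#' Write the report bundle for a power result
#'
#' Writes `cells.csv` (per-cell summaries), `replicates.csv` (per-replicate
#' estimates) and three plots: the simulated-series spaghetti, the
#' rate-ratio caterpillar with the true value marked, and power against
#' unexplained variability.
#'
#' @param result a `power_result`.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
summarize_report <- function(result, out_dir) {
  if (nrow(result) == 0) stop_its("Empty power result.", "domain")
  ok <- tryCatch({
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    file.access(out_dir, mode = 2) == 0
  }, error = function(e) FALSE)
  if (!ok) stop_its(sprintf("Cannot write to `%s`.", out_dir), "io")
  paths <- c(
    cells = file.path(out_dir, "cells.csv"),
    replicates = file.path(out_dir, "replicates.csv"),
    spaghetti = file.path(out_dir, "simulated_series.pdf"),
    caterpillar = file.path(out_dir, "rate_ratios.pdf"),
    power = file.path(out_dir, "power_vs_sd.pdf")
  )
  readr::write_csv(as_tibble(result), paths["cells"])
  readr::write_csv(power_replicates(result), paths["replicates"])
  ggplot2::ggsave(paths["spaghetti"], plot_simulated_series(result),
                  width = 8, height = 5)
  ggplot2::ggsave(paths["caterpillar"], plot_estimates(result),
                  width = 8, height = 5)
  ggplot2::ggsave(paths["power"], autoplot(result), width = 7, height = 5)
  invisible(paths)
}
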