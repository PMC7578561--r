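#' Spaghetti plot of simulated series
#'
#' Overlays the retained simulated replicates (grey lines) for each cell of
#' a power result, faceted by rate ratio and baseline drop.
#'
#' @param result a `power_result` (with retained series) or a long tibble
#'   with columns `replicate`, `date`, `count` (optionally `irr_true`,
#'   `baseline_drop`).
#' @return a ggplot object.
#' @export
plot_simulated_series <- function(result) {
  df <- if (inherits(result, "power_result")) attr(result, "series_sample") else result
  if (is.null(df) || nrow(df) == 0) stop_its("No retained simulated series to plot.", "domain")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$date, .data$count,
                                        group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.25, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "Simulated monthly count") +
    ggplot2::theme_minimal()
  if (all(c("irr_true", "baseline_drop") %in% names(df)) &&
      dplyr::n_distinct(df$irr_true, df$baseline_drop) > 1) {
    p <- p + ggplot2::facet_grid(
      rows = ggplot2::vars(.data$baseline_drop),
      cols = ggplot2::vars(.data$irr_true), labeller = "label_both"
    )
  }
  p
}

#' Caterpillar plot of per-replicate rate-ratio estimates
#'
#' Replicates are ordered by their estimate; the true rate ratio is drawn
#' as a red dashed line and the null (1) as a solid grey line.
#'
#' @param result a `power_result`, or a replicate tibble with `irr`,
#'   `ci_low`, `ci_high` (and optionally `irr_true`).
#' @param cell optional 1-row tibble/list with `irr` and `baseline_drop`
#'   picking a single cell of a multi-cell result (default: first cell).
#' @return a ggplot object.
#' @export
plot_estimates <- function(result, cell = NULL) {
  if (inherits(result, "power_result")) {
    reps <- power_replicates(result)
    cell <- cell %||% list(irr = result$irr[1], baseline_drop = result$baseline_drop[1])
    reps <- reps[reps$irr_true == cell$irr & reps$baseline_drop == cell$baseline_drop, ]
  } else {
    reps <- result
  }
  reps <- reps[order(reps$irr), ]
  reps$rank <- seq_len(nrow(reps))
  truth <- if ("irr_true" %in% names(reps)) reps$irr_true[1] else NA_real_
  p <- ggplot2::ggplot(reps, ggplot2::aes(.data$rank, .data$irr)) +
    ggplot2::geom_hline(yintercept = 1, colour = "grey50") +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                            alpha = 0.35) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "Replicate (ordered by estimate)",
                  y = "Rate ratio at ramp end (95% CI)") +
    ggplot2::theme_minimal()
  if (is.finite(truth)) {
    p <- p + ggplot2::geom_hline(yintercept = truth, colour = "red",
                                 linetype = "dashed")
  }
  p
}

#' Plot a power result
#'
#' Power per cell against unexplained variability (default), mean monthly
#' count, or the specified rate ratio.
#'
#' @param object a `power_result`.
#' @param x which characteristic to put on the x axis.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot power_result
#' @export
autoplot.power_result <- function(object,
                                  x = c("unexplained_sd", "mean_count", "irr"),
                                  ...) {
  x <- match.arg(x)
  df <- as_tibble(object)
  lab <- switch(x,
    unexplained_sd = "Unexplained variability (SD of random intercept)",
    mean_count = "Mean monthly count (log scale)",
    irr = "Specified rate ratio"
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[x]], .data$power)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$irr),
                                     shape = factor(.data$baseline_drop)),
                        size = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = lab, y = "Power", colour = "Rate ratio",
                  shape = "Years dropped") +
    ggplot2::theme_minimal()
  if (x == "mean_count") p <- p + ggplot2::scale_x_log10()
  p
}
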