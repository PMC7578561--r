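# Design matrix for the seasonal baseline model:
#   log-rate = b0 + b1 * t + b2 cos(2*pi*t/12) + b3 sin(2*pi*t/12)
#            + b4 cos(2*pi*t/6) + b5 sin(2*pi*t/6) [+ control terms]
# t counts months since `origin` (0-based), so harmonics keep their phase
# when the post period continues a baseline design.

#' Build the seasonal regression design
#'
#' @param series a `monthly_series`.
#' @param control_mode `"none"`, `"covariate"` (controls enter as
#'   `log(count + 0.5)` columns) or `"offset"` (a single control enters as a
#'   fixed `log(count)` offset with unit coefficient).
#' @param origin month that defines `t = 0`; defaults to the series start.
#'   Pass the baseline start when building a post-period design so the time
#'   index and harmonic phase continue the baseline numbering.
#' @return a `design_matrix`: list with the model matrix `X`, the `offset`
#'   vector, the time index `t` and the dates.
#' @export
build_design <- function(series, control_mode = c("none", "covariate", "offset"),
                         origin = NULL) {
  control_mode <- match.arg(control_mode)
  origin <- if (is.null(origin)) series$date[1L] else parse_month(origin)
  t <- as.numeric(month_diff(series$date, origin))
  theta <- 2 * pi * t
  X <- cbind(
    intercept = 1,
    time = t,
    cos12 = cos(theta / 12),
    sin12 = sin(theta / 12),
    cos6 = cos(theta / 6),
    sin6 = sin(theta / 6)
  )
  offset <- rep(0, nrow(X))
  ctrl <- series_controls(series)
  if (control_mode == "covariate") {
    for (nm in ctrl) {
      X <- cbind(X, log(series[[nm]] + 0.5))
      colnames(X)[ncol(X)] <- paste0("log_", nm)
    }
  } else if (control_mode == "offset") {
    if (length(ctrl) != 1L) {
      stop_its("Offset mode requires exactly one control series.", "config")
    }
    ctl <- series[[ctrl]]
    if (any(ctl == 0)) {
      stop_its(
        sprintf("Control `%s` has a zero count (month %s); log offset undefined.",
                ctrl, format(series$date[which(ctl == 0)[1]], "%Y-%m")),
        "value"
      )
    }
    offset <- log(ctl)
  }
  structure(
    list(X = X, offset = offset, t = t, dates = series$date,
         control_mode = control_mode, origin = origin),
    class = "design_matrix"
  )
}

design_columns <- function(design) colnames(design$X)
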