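# A monthly_series is a tibble with a `date` column (first-of-month Date),
# an `outcome` column of counts, and zero or more control count columns.
# Attributes: `controls` (control column names), `outcome_name` (the name
# the outcome had in the source file, used when writing), `label`.

new_monthly_series <- function(df, controls, outcome_name = "outcome", label = NULL) {
  structure(
    as_tibble(df),
    controls = controls,
    outcome_name = outcome_name,
    label = label,
    class = c("monthly_series", class(as_tibble(df)))
  )
}

validate_monthly_series <- function(x) {
  if (!all(c("date", "outcome") %in% names(x))) {
    stop_its("A monthly series needs `date` and `outcome` columns.", "schema")
  }
  d <- x$date
  if (anyNA(d)) stop_its("Missing dates are not allowed.", "parse")
  if (any(format(d, "%d") != "01")) {
    stop_its("Series dates must be aligned to month starts.", "contiguity")
  }
  if (nrow(x) > 1L) {
    gaps <- month_diff(d[-1L], d[-length(d)])
    if (any(gaps == 0L)) {
      stop_its(
        sprintf("Duplicate month %s in series.", format(d[which(gaps == 0L)[1] + 1L], "%Y-%m")),
        "contiguity"
      )
    }
    if (any(gaps != 1L)) {
      i <- which(gaps != 1L)[1]
      stop_its(
        sprintf(
          "Series is not a gap-free monthly grid: %s is followed by %s.",
          format(d[i], "%Y-%m"), format(d[i + 1L], "%Y-%m")
        ),
        "contiguity"
      )
    }
  }
  count_cols <- c("outcome", series_controls(x))
  for (nm in count_cols) {
    if (anyNA(x[[nm]])) {
      stop_its(sprintf("Missing values in `%s` are not imputed; supply a complete series.", nm), "value")
    }
    if (!is_count_vector(x[[nm]])) {
      stop_its(sprintf("Column `%s` must contain nonnegative integer counts.", nm), "value")
    }
  }
  x
}

series_controls <- function(series) attr(series, "controls") %||% character()

series_label <- function(series) attr(series, "label")

#' Construct a monthly count series
#'
#' @param dates vector of dates (one per month, gap-free); coerced to
#'   month starts via [parse_month()] rules.
#' @param outcome nonnegative integer counts, one per month.
#' @param controls optional named list (or data frame) of control count
#'   series aligned to `dates`.
#' @param label free-text identifier carried through reports.
#' @param outcome_name name used for the outcome column when writing to file.
#' @return a `monthly_series` tibble with columns `date`, `outcome` and one
#'   column per control.
#' @export
#' @examples
#' s <- monthly_series(seq(as.Date("2003-01-01"), by = "month", length.out = 24),
#'                     rpois(24, 100))
monthly_series <- function(dates, outcome, controls = NULL, label = NULL,
                           outcome_name = "outcome") {
  dates <- parse_month(dates)
  df <- tibble(date = dates, outcome = as.numeric(outcome))
  ctrl_names <- character()
  if (!is.null(controls) && length(controls)) {
    controls <- as.list(controls)
    if (is.null(names(controls)) || any(names(controls) == "")) {
      stop_its("Control series must be named.", "schema")
    }
    for (nm in names(controls)) df[[nm]] <- as.numeric(controls[[nm]])
    ctrl_names <- names(controls)
  }
  validate_monthly_series(new_monthly_series(df, ctrl_names, outcome_name, label))
}

#' Read a monthly count time series from CSV or Excel
#'
#' Reads a delimited or spreadsheet file, picks out the date, outcome and
#' control columns, and returns a validated [monthly_series()]. Dates must
#' be ISO (`YYYY-MM-DD` or `YYYY-MM`) unless `date_format` states another
#' dialect explicitly; ambiguous day/month orders are never guessed.
#'
#' @param path path to a `.csv` or `.xlsx` file with a header row.
#' @param date_col,outcome_col column names for the date and the outcome.
#' @param control_cols character vector of control column names (may be empty).
#' @param date_format optional `strptime` format for non-ISO dates.
#' @param sheet sheet name or index for Excel input (default first).
#' @param label optional identifier for the series.
#' @return a `monthly_series` tibble.
#' @export
read_timeseries <- function(path, date_col, outcome_col,
                            control_cols = character(),
                            date_format = NULL, sheet = 1, label = NULL) {
  if (!file.exists(path)) stop_its(sprintf("File not found: %s", path), "schema")
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop_its("Reading Excel files requires the readxl package.", "config")
    }
    readxl::read_excel(path, sheet = sheet)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  wanted <- c(date_col, outcome_col, control_cols)
  missing_cols <- setdiff(wanted, names(raw))
  if (length(missing_cols)) {
    stop_its(
      sprintf("Column(s) not found in %s: %s", basename(path),
              paste0("`", missing_cols, "`", collapse = ", ")),
      "schema"
    )
  }
  monthly_series(
    dates = parse_month(raw[[date_col]], date_format),
    outcome = check_counts_col(raw[[outcome_col]], outcome_col),
    controls = stats::setNames(
      lapply(control_cols, function(nm) check_counts_col(raw[[nm]], nm)),
      control_cols
    ),
    label = label %||% basename(path),
    outcome_name = outcome_col
  )
}

check_counts_col <- function(x, name) {
  if (anyNA(x)) {
    stop_its(sprintf("Missing values in `%s` at row %d; counts are not imputed.",
                     name, which(is.na(x))[1]), "value")
  }
  if (!is_count_vector(x)) {
    stop_its(sprintf("Column `%s` must contain nonnegative integer counts.", name), "value")
  }
  x
}

#' Write a monthly series to CSV
#'
#' Columns: date (ISO), the outcome under its original name, one column per
#' control. Re-reading with [read_timeseries()] restores the series exactly.
#'
#' @param series a `monthly_series`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path) {
  out <- as_tibble(series)
  names(out)[names(out) == "outcome"] <- attr(series, "outcome_name") %||% "outcome"
  readr::write_csv(out, path)
  invisible(path)
}

#' Define the analysis window
#'
#' @param intro_date calendar month of vaccine introduction (the first ramp
#'   month; the effect is 0 in this month and declines from the next).
#' @param eval_end last calendar month of the evaluation period.
#' @param ramp_months months over which the vaccine effect reaches its final
#'   rate ratio (default 24; 1 gives a step change).
#' @return an `analysis_window` object.
#' @export
analysis_window <- function(intro_date, eval_end, ramp_months = 24) {
  intro_date <- parse_month(intro_date)
  eval_end <- parse_month(eval_end)
  if (length(intro_date) != 1L || length(eval_end) != 1L) {
    stop_its("`intro_date` and `eval_end` must be single months.", "domain")
  }
  if (eval_end < intro_date) {
    stop_its("`eval_end` must not precede `intro_date`.", "range")
  }
  if (!is.numeric(ramp_months) || ramp_months < 1) {
    stop_its("`ramp_months` must be a positive integer.", "domain")
  }
  structure(
    list(intro_date = intro_date, eval_end = eval_end,
         ramp_months = as.integer(ramp_months)),
    class = "analysis_window"
  )
}

#' Split a series into pre- and post-introduction periods
#'
#' The pre period holds all months strictly before `intro_date`; the post
#' period holds `intro_date` through `eval_end` inclusive.
#'
#' @param series a `monthly_series`.
#' @param window an [analysis_window()].
#' @return a list with elements `pre` and `post`, both `monthly_series`.
#' @export
split_periods <- function(series, window) {
  d <- series$date
  if (window$intro_date <= d[1L]) {
    stop_its("`intro_date` must fall strictly after the series start (the baseline would be empty).", "range")
  }
  if (window$intro_date > d[length(d)]) {
    stop_its("`intro_date` is after the series end.", "range")
  }
  if (window$eval_end > d[length(d)]) {
    stop_its("`eval_end` is after the series end.", "range")
  }
  pre <- series[d < window$intro_date, , drop = FALSE]
  post <- series[d >= window$intro_date & d <= window$eval_end, , drop = FALSE]
  list(
    pre = restore_series(pre, series),
    post = restore_series(post, series)
  )
}

restore_series <- function(df, template) {
  validate_monthly_series(new_monthly_series(
    df, series_controls(template),
    attr(template, "outcome_name") %||% "outcome", series_label(template)
  ))
}

#' Drop the earliest baseline years
#'
#' Removes the first `12 * years_dropped` months, emulating shorter
#' pre-vaccine records when studying how baseline length affects power.
#'
#' @param series a `monthly_series`.
#' @param years_dropped nonnegative integer number of years to drop.
#' @return the shortened `monthly_series`.
#' @export
truncate_baseline <- function(series, years_dropped) {
  if (!is.numeric(years_dropped) || years_dropped < 0 ||
      abs(years_dropped - round(years_dropped)) > 1e-8) {
    stop_its("`years_dropped` must be a nonnegative integer.", "domain")
  }
  k <- 12L * as.integer(round(years_dropped))
  if (k >= nrow(series)) {
    stop_its(
      sprintf("Dropping %d months from a %d-month series leaves nothing.", k, nrow(series)),
      "range"
    )
  }
  if (k == 0L) return(series)
  restore_series(series[-seq_len(k), , drop = FALSE], series)
}

#' @export
print.monthly_series <- function(x, ...) {
  lbl <- series_label(x)
  cat(sprintf(
    "<monthly_series> %d months (%s to %s)%s\n",
    nrow(x), format(x$date[1], "%Y-%m"), format(x$date[nrow(x)], "%Y-%m"),
    if (is.null(lbl)) "" else paste0(" - ", lbl)
  ))
  ctrl <- series_controls(x)
  if (length(ctrl)) cat("controls:", paste(ctrl, collapse = ", "), "\n")
  NextMethod()
}
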