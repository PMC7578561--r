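# Calendar-month arithmetic. All series dates are normalized to the first
# day of the month; within-month day information is discarded on input.

floor_month <- function(x) {
  as.Date(format(as.Date(x), "%Y-%m-01"))
}

month_seq <- function(from, length_out) {
  seq(floor_month(from), by = "month", length.out = length_out)
}

# Signed number of calendar months from `b` to `a`.
month_diff <- function(a, b) {
  a <- as.POSIXlt(a)
  b <- as.POSIXlt(b)
  (a$year - b$year) * 12L + (a$mon - b$mon)
}

#' Parse calendar-month dates
#'
#' Accepts `Date`/`POSIXct` vectors, ISO strings (`"2011-01-01"` or
#' `"2011-01"`), or any format given explicitly through `date_format`
#' (a [base::strptime()] template). Day-first or month-first strings are
#' never guessed: they parse only when `date_format` says so. Parsed dates
#' are floored to the first day of the month.
#'
#' @param x vector of dates or date strings.
#' @param date_format optional `strptime` format string (e.g. `"%d/%m/%Y"`).
#' @return a `Date` vector aligned to month starts.
#' @keywords internal
parse_month <- function(x, date_format = NULL) {
  if (inherits(x, "Date") || inherits(x, "POSIXt")) {
    return(floor_month(as.Date(x)))
  }
  if (!is.character(x)) {
    stop_its("Dates must be Date, POSIXct or character.", "parse")
  }
  x <- trimws(x)
  if (!is.null(date_format)) {
    out <- as.Date(x, format = date_format)
  } else {
    iso <- ifelse(grepl("^\\d{4}-\\d{1,2}$", x), paste0(x, "-01"), x)
    out <- as.Date(iso, format = "%Y-%m-%d")
  }
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop_its(
      sprintf(
        "Could not parse date '%s' at row %d%s.",
        x[bad[1]], bad[1],
        if (is.null(date_format)) " (ISO dates expected; pass `date_format` for other dialects)" else ""
      ),
      "parse"
    )
  }
  if (anyNA(x)) stop_its("Missing date values are not allowed.", "parse")
  floor_month(out)
}
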