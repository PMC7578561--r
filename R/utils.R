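# Condition helpers: every user-facing error carries a subclass so callers
# (and tests) can branch on the failure mode rather than matching messages.

stop_its <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("itspower_error_", class), "itspower_error"), ...)
}

is_count_vector <- function(x, tol = 1e-8) {
  is.numeric(x) && !anyNA(x) && all(is.finite(x)) &&
    all(abs(x - round(x)) < tol) && all(x >= 0)
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_its(sprintf("`%s` must be a single finite number.", name), "domain")
  }
  invisible(x)
}
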