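#' @importFrom rlang abort warn .data
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# run expr with an isolated RNG stream; the caller's RNG state is untouched
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer.", class = "calmscape_spec_error")
  }
  withr::with_seed(as.integer(seed), expr)
}

stop_spec <- function(msg) abort(msg, class = "calmscape_spec_error")
stop_input <- function(msg) abort(msg, class = "calmscape_input_error")

check_fraction <- function(x, name, lo = 0, hi = 1,
                           lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    all(if (lo_open) x > lo else x >= lo) &&
    all(if (hi_open) x < hi else x <= hi)
  if (!ok) {
    stop_spec(sprintf("`%s` must be in %s%g, %g%s.", name,
                      if (lo_open) "(" else "[", lo, hi,
                      if (hi_open) ")" else "]"))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) ||
      x != round(x) || x < min) {
    stop_spec(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  as.integer(x)
}

# split a string into single characters
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
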