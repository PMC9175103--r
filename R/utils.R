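# Internal helpers shared across modules.

#' Round half-up to a fixed number of decimals
#'
#' Base `round()` rounds half to even; clinical reports conventionally round
#' half away from zero, so 71.875 prints as 71.9.
#'
#' @param x numeric vector
#' @param digits decimal places (default 1)
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Slice note text by a 0-based half-open [start, end) character interval.
span_text <- function(text, start, end) {
  substr(text, start + 1L, end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Vectorised NULL/NA-safe scalar check
is_scalar_na <- function(x) length(x) == 1L && is.na(x)

# Stable lowercase (locale-independent for ASCII clinical text)
lc <- function(x) tolower(x)

new_id <- function(prefix, i) sprintf("%s%04d", prefix, i)

as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x)
}
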