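# Evaluation statistics: 2x2 performance metrics and binomial rates with
# exact (Clopper-Pearson) or Wilson 95% confidence intervals, printed to
# one decimal with half-up rounding.

#' Exact binomial confidence interval
#'
#' Clopper-Pearson interval from beta-distribution quantiles:
#' lower = qbeta(alpha/2, x, n-x+1), upper = qbeta(1-alpha/2, x+1, n-x),
#' with the conventional 0/1 endpoints at the boundaries.
#'
#' @param x successes
#' @param n trials
#' @param conf confidence level (default 0.95)
#' @return numeric `c(lower, upper)` on the proportion scale
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  a <- 1 - conf
  lo <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(lo, hi)
}

#' Wilson score confidence interval
#' @inheritParams clopper_pearson
#' @return numeric `c(lower, upper)` on the proportion scale
#' @export
wilson_interval <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, center - half), min(1, center + half))
}

#' Binomial rate with confidence interval
#'
#' @param numerator,denominator integer counts,
#'   `0 <= numerator <= denominator`
#' @param ci_method `"clopper_pearson"` (default) or `"wilson"`
#' @param conf confidence level
#' @return a `rate_ci` list: `numerator`, `denominator`, `rate_percent`
#'   (1 decimal, half-up), `ci_low_percent`, `ci_high_percent`, `method`
#' @export
rate_with_ci <- function(numerator, denominator,
                         ci_method = c("clopper_pearson", "wilson"),
                         conf = 0.95) {
  ci_method <- match.arg(ci_method)
  if (denominator <= 0)
    stop("denominator must be positive")
  if (numerator < 0 || numerator > denominator)
    stop("numerator must lie in [0, denominator]")
  ci <- switch(ci_method,
               clopper_pearson = clopper_pearson(numerator, denominator, conf),
               wilson = wilson_interval(numerator, denominator, conf))
  structure(list(numerator = as.integer(numerator),
                 denominator = as.integer(denominator),
                 rate_percent = round_half_up(100 * numerator / denominator),
                 ci_low_percent = round_half_up(100 * ci[1]),
                 ci_high_percent = round_half_up(100 * ci[2]),
                 method = ci_method),
            class = "rate_ci")
}

#' @export
print.rate_ci <- function(x, ...) {
  cat(sprintf("%.1f%% (%d/%d; 95%% CI %.1f%%-%.1f%%, %s)\n",
              x$rate_percent, x$numerator, x$denominator,
              x$ci_low_percent, x$ci_high_percent, x$method))
  invisible(x)
}

#' Chart-confirmation rate
#'
#' Proportion of NLP-identified cases confirmed by record review, as a
#' percentage to one decimal with an exact binomial interval.
#'
#' @param n_confirmed confirmed cases
#' @param n_identified NLP-identified cases (> 0)
#' @param ci_method interval method
#' @return a `rate_ci`
#' @export
compute_confirmation_rate <- function(n_confirmed, n_identified,
                                      ci_method = "clopper_pearson") {
  if (n_identified <= 0) stop("n_identified must be positive")
  if (n_confirmed < 0 || n_confirmed > n_identified)
    stop("n_confirmed must lie in [0, n_identified]")
  rate_with_ci(n_confirmed, n_identified, ci_method)
}

#' 2x2 classification performance metrics
#'
#' Sensitivity, specificity, positive and negative predictive value with
#' 95% confidence intervals. A metric whose denominator is zero is reported
#' as undefined (`NA`), not an error.
#'
#' @param counts list or vector with `tp`, `fp`, `tn`, `fn`
#' @param ci_method `"clopper_pearson"` (default) or `"wilson"`
#' @return a `metric_set`: one `rate_ci` (or `NA`) per metric
#' @export
compute_metrics <- function(counts, ci_method = "clopper_pearson") {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  mk <- function(x, n) if (n > 0) rate_with_ci(x, n, ci_method) else NA
  structure(list(sensitivity = mk(tp, tp + fn),
                 specificity = mk(tn, tn + fp),
                 ppv = mk(tp, tp + fp),
                 npv = mk(tn, tn + fn),
                 counts = list(tp = tp, fp = fp, tn = tn, fn = fn),
                 method = ci_method),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    cat(sprintf("%-12s", m))
    if (identical(x[[m]], NA) || all(is.na(x[[m]][1]))) cat("undefined\n")
    else print(x[[m]])
  }
  invisible(x)
}
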