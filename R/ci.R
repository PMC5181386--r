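#' Wilson score interval for a binomial proportion
#'
#' @param x Number of events.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric `c(lower, upper)` on the probability scale.
#' @export
wilson_interval <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Prevalence with Wilson 95% confidence interval
#'
#' @param numerator Count of respondents with the attribute.
#' @param denominator Total respondents.
#' @param conf Confidence level.
#' @param label Optional label carried into the output.
#' @return One-row tibble: `label` (if given), `numerator`, `denominator`,
#'   `percent`, `ci_low`, `ci_high` (all percent-scale, full precision; round
#'   with [round_half_up()] for display).
#' @examples
#' prevalence(292, 483)
#' @export
prevalence <- function(numerator, denominator, conf = 0.95, label = NULL) {
  if (denominator <= 0) stop("denominator must be > 0", call. = FALSE)
  if (numerator < 0 || numerator > denominator) {
    stop("numerator must lie in [0, denominator]", call. = FALSE)
  }
  ci <- wilson_interval(numerator, denominator, conf)
  out <- tibble::tibble(
    numerator = numerator,
    denominator = denominator,
    percent = 100 * numerator / denominator,
    ci_low = 100 * ci[["lower"]],
    ci_high = 100 * ci[["upper"]]
  )
  if (!is.null(label)) out <- tibble::add_column(out, label = label, .before = 1)
  out
}

#' Difference between two prevalences with Newcombe score interval
#'
#' The interval is Newcombe's hybrid score method: Wilson limits are computed
#' for each proportion and combined, which behaves well at small samples and
#' near 0% or 100% where the Wald interval degenerates.
#'
#' @param x_pos,n_pos Events and total in the "positive" (exposed) group.
#' @param x_neg,n_neg Events and total in the "negative" (reference) group.
#' @param conf Confidence level.
#' @return One-row tibble: `p_positive`, `p_negative`, `difference`,
#'   `ci_low`, `ci_high`, `n_positive`, `n_negative` (percent scale).
#' @examples
#' prevalence_difference(75, 100, 50, 100)
#' @export
prevalence_difference <- function(x_pos, n_pos, x_neg, n_neg, conf = 0.95) {
  if (n_pos <= 0 || n_neg <= 0) stop("both group totals must be > 0", call. = FALSE)
  p1 <- x_pos / n_pos
  p2 <- x_neg / n_neg
  w1 <- wilson_interval(x_pos, n_pos, conf)
  w2 <- wilson_interval(x_neg, n_neg, conf)
  d <- p1 - p2
  lower <- d - sqrt((p1 - w1[["lower"]])^2 + (w2[["upper"]] - p2)^2)
  upper <- d + sqrt((w1[["upper"]] - p1)^2 + (p2 - w2[["lower"]])^2)
  tibble::tibble(
    p_positive = 100 * p1,
    p_negative = 100 * p2,
    difference = 100 * d,
    ci_low = 100 * lower,
    ci_high = 100 * upper,
    n_positive = n_pos,
    n_negative = n_neg
  )
}
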