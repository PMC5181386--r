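#' Round half away from zero
#'
#' Display rounding used throughout the report tables: ties are rounded away
#' from zero (so 60.45 -> 60.5), unlike [base::round()]'s banker's rounding.
#' Internal computation is always at full precision; this is applied only when
#' formatting.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

assert_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_config(field, "probabilities must lie in [0, 1]")
  }
  invisible(x)
}

# expectation of plogis(intercept + x) where x ~ N(mu, sd), summed over
# mixture components with weights w
logit_normal_mean <- function(intercept, mu, sd, w = rep(1 / length(mu), length(mu))) {
  stopifnot(length(mu) == length(w), all(sd >= 0))
  if (length(sd) == 1L) sd <- rep(sd, length(mu))
  comp <- vapply(seq_along(mu), function(k) {
    if (sd[k] < 1e-12) return(stats::plogis(intercept + mu[k]))
    stats::integrate(
      function(z) stats::plogis(intercept + z) * stats::dnorm(z, mu[k], sd[k]),
      lower = mu[k] - 10 * sd[k], upper = mu[k] + 10 * sd[k],
      rel.tol = 1e-10
    )$value
  }, numeric(1))
  sum(w * comp)
}

# solve for the intercept giving a target marginal event probability when the
# linear predictor is intercept + x, x ~ mixture of normals
calibrate_intercept <- function(target, mu, sd, w = rep(1 / length(mu), length(mu))) {
  stopifnot(target > 0, target < 1)
  stats::uniroot(
    function(a) logit_normal_mean(a, mu, sd, w) - target,
    interval = c(-25, 25), tol = 1e-9
  )$root
}
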