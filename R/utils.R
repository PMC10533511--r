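# Shared numeric helpers.

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used for
#' the printed percentages and odds ratios in clinical tables), as opposed to
#' the round-half-even rule of [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(9.594, 1) # 9.6
#' round_half_up(0.25, 1)  # 0.3, where round(0.25, 1) gives 0.2
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

# Truncated-normal draws via inverse-CDF; sd = 0 collapses to the mean.
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (all(sd == 0)) {
    return(rep_len(pmin(pmax(mean, lower), upper), n))
  }
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

# Mean and variance of a truncated normal; used to derive planted truth
# without simulation.
tnorm_moments <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    return(list(mean = mean, var = 0))
  }
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- pnorm(b) - pnorm(a)
  da <- dnorm(a)
  db <- dnorm(b)
  mu <- mean + sd * (da - db) / z
  term_a <- if (is.finite(a)) a * da else 0
  term_b <- if (is.finite(b)) b * db else 0
  v <- sd^2 * (1 + (term_a - term_b) / z - ((da - db) / z)^2)
  list(mean = mu, var = v)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}
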