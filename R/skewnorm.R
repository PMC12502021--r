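# Skew-normal distribution (location xi, scale omega, shape alpha), used for
# midday sun-leaf temperatures, which are right-skewed. Density is
# 2/omega * dnorm(z) * pnorm(alpha * z), z = (x - xi)/omega; sampling uses the
# exact half-normal representation Z = delta*|U0| + sqrt(1-delta^2)*U1.

#' Skew-normal density
#' @param x quantiles.
#' @param xi,omega,alpha location, scale (> 0) and shape parameters.
#' @return density values.
#' @export
dskewnorm <- function(x, xi = 0, omega = 1, alpha = 0) {
  stopifnot(omega > 0)
  z <- (x - xi) / omega
  2 / omega * stats::dnorm(z) * stats::pnorm(alpha * z)
}

#' Skew-normal random draws
#' @param n number of draws.
#' @inheritParams dskewnorm
#' @return numeric vector of length `n`.
#' @export
rskewnorm <- function(n, xi = 0, omega = 1, alpha = 0) {
  stopifnot(omega > 0)
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- stats::rnorm(n); u1 <- stats::rnorm(n)
  xi + omega * (delta * abs(u0) + sqrt(1 - delta^2) * u1)
}

#' Mean of the upper quartile of a skew-normal distribution
#'
#' Population analogue of the upper-quartile-mean leaf temperature statistic:
#' the conditional mean above the 75th percentile, computed by numerical
#' integration (no closed form). Used to calibrate the generator's location
#' so a simulated species-site hits a target upper-quartile mean.
#'
#' @inheritParams dskewnorm
#' @return scalar conditional mean.
#' @export
skewnorm_upper_quartile_mean <- function(xi = 0, omega = 1, alpha = 0) {
  cdf <- function(x) stats::integrate(dskewnorm, -Inf, x, xi = xi,
                                      omega = omega, alpha = alpha,
                                      rel.tol = 1e-10)$value
  lo <- xi - 10 * omega; hi <- xi + 10 * omega
  q75 <- stats::uniroot(function(x) cdf(x) - 0.75, c(lo, hi),
                        tol = 1e-10)$root
  stats::integrate(function(x) x * dskewnorm(x, xi, omega, alpha),
                   q75, hi, rel.tol = 1e-10)$value / 0.25
}
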