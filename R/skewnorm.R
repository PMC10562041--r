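# Skew-normal distribution (Azzalini parameterization: location xi, scale
# omega, shape alpha) used as the noise family for scheduled-dose coverage
# deficits, which are left-skewed. Only what the generator needs: density,
# CDF, quantile, sampler, and a median/IQR calibration.

#' Skew-normal density
#' @param x Quantiles.
#' @param xi,omega,alpha Location, scale (> 0) and shape.
#' @return Density values.
#' @export
dskewnorm <- function(x, xi = 0, omega = 1, alpha = 0) {
  stopifnot(omega > 0)
  z <- (x - xi) / omega
  2 / omega * stats::dnorm(z) * stats::pnorm(alpha * z)
}

# Owen's T function T(h, a) by direct quadrature of its defining integral.
owen_t <- function(h, a) {
  if (a == 0) return(0)
  if (a < 0) return(-owen_t(h, -a))
  f <- function(x) exp(-0.5 * h^2 * (1 + x^2)) / (1 + x^2)
  stats::integrate(f, 0, a, rel.tol = 1e-10)$value / (2 * pi)
}

#' Skew-normal CDF
#' @inheritParams dskewnorm
#' @param q Quantiles.
#' @return Probabilities.
#' @export
pskewnorm <- function(q, xi = 0, omega = 1, alpha = 0) {
  stopifnot(omega > 0)
  z <- (q - xi) / omega
  vapply(z, function(zi) stats::pnorm(zi) - 2 * owen_t(zi, alpha), numeric(1))
}

#' Skew-normal quantile function
#' @inheritParams dskewnorm
#' @param p Probabilities in (0, 1).
#' @return Quantiles.
#' @export
qskewnorm <- function(p, xi = 0, omega = 1, alpha = 0) {
  stopifnot(all(p > 0 & p < 1), omega > 0)
  vapply(p, function(pi) {
    z <- stats::uniroot(function(z) pskewnorm(z, alpha = alpha) - pi,
                        lower = -12, upper = 12, tol = 1e-10)$root
    xi + omega * z
  }, numeric(1))
}

#' Sample from a skew-normal distribution
#'
#' Uses the convolution representation
#' `Z = delta * |U0| + sqrt(1 - delta^2) * U1` with independent standard
#' normals and `delta = alpha / sqrt(1 + alpha^2)`.
#'
#' @param n Sample size.
#' @inheritParams dskewnorm
#' @return Numeric vector of draws.
#' @export
rskewnorm <- function(n, xi = 0, omega = 1, alpha = 0) {
  stopifnot(omega > 0)
  delta <- alpha / sqrt(1 + alpha^2)
  z <- delta * abs(stats::rnorm(n)) + sqrt(1 - delta^2) * stats::rnorm(n)
  xi + omega * z
}

#' Calibrate a skew-normal to a target median and IQR
#'
#' Given the shape `alpha`, solves for the location and scale such that the
#' distribution has exactly the requested median and interquartile range:
#' `omega = IQR / (z75 - z25)`, `xi = median - omega * z50`, where `z_p` are
#' standard skew-normal quantiles.
#'
#' @param median_target,iqr_target Target median and IQR (`iqr_target > 0`).
#' @param alpha Shape parameter (sign sets the skew direction).
#' @return List with `xi`, `omega`, `alpha` and the quartiles `q25`, `q50`,
#'   `q75` of the calibrated distribution.
#' @export
calibrate_skewnorm <- function(median_target, iqr_target, alpha = 0) {
  stopifnot(iqr_target > 0)
  z <- qskewnorm(c(0.25, 0.5, 0.75), alpha = alpha)
  omega <- iqr_target / (z[3] - z[1])
  xi <- median_target - omega * z[2]
  list(xi = xi, omega = omega, alpha = alpha,
       q25 = xi + omega * z[1], q50 = median_target, q75 = xi + omega * z[3])
}
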