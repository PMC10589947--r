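#' Wrap an angle to the interval (-pi, pi]
#'
#' Canonical support for turning angles. The half-open convention maps
#' \code{-pi} to \code{+pi}; the choice of which endpoint is closed is
#' arbitrary but applied consistently throughout the package.
#'
#' @param angle Numeric vector of angles in radians. Must be finite.
#' @return Numeric vector of the same length, congruent to `angle` modulo
#'   `2*pi`, in `(-pi, pi]`.
#' @examples
#' wrap_to_pi(3 * pi / 2)  # -pi/2
#' wrap_to_pi(-pi)         # pi
#' @export
wrap_to_pi <- function(angle) {
  if (!is.numeric(angle) || any(!is.finite(angle))) {
    abort("`angle` must be finite numeric.")
  }
  out <- angle - 2 * pi * floor(angle / (2 * pi) + 0.5)
  # floor(x + .5) rounds halves up, so exact -pi lands on -pi; push to +pi
  out[out <= -pi] <- pi
  out
}

check_wc_params <- function(gamma, kappa) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma)) {
    abort("wrapped Cauchy location `gamma` must be a finite scalar.")
  }
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
      kappa < 0 || kappa >= 1) {
    abort("wrapped Cauchy concentration `kappa` must lie in [0, 1).")
  }
  invisible(NULL)
}

#' Wrapped Cauchy density on (-pi, pi]
#'
#' Density \deqn{f(a) = \frac{1 - \kappa^2}{2\pi(1 + \kappa^2 -
#' 2\kappa\cos(a - \gamma))}} with location \eqn{\gamma} and concentration
#' \eqn{\kappa \in [0, 1)}. At \eqn{\kappa = 0} the distribution is uniform
#' on the circle; as \eqn{\kappa \to 1} it concentrates at \eqn{\gamma}.
#'
#' @param a Numeric vector of angles in radians (any real value; wrapped
#'   internally).
#' @param gamma Location parameter, radians.
#' @param kappa Concentration, in `[0, 1)`.
#' @param log If `TRUE` return the log-density.
#' @return Numeric vector of (log-)densities.
#' @examples
#' dwrappedcauchy(0.7, gamma = 0.2, kappa = 0, log = TRUE)  # log(1/(2*pi))
#' @export
dwrappedcauchy <- function(a, gamma, kappa, log = FALSE) {
  check_wc_params(gamma, kappa)
  ld <- log1p(-kappa^2) -
    log(2 * pi) -
    log1p(kappa^2 - 2 * kappa * cos(a - gamma))
  if (log) ld else exp(ld)
}

#' Sample from the wrapped Cauchy distribution
#'
#' Draws a linear Cauchy with scale \eqn{-\log\kappa} and wraps it; at
#' \eqn{\kappa = 0} draws uniform angles. Uses R's RNG stream.
#'
#' @param n Number of draws.
#' @param gamma Location, radians.
#' @param kappa Concentration in `[0, 1)`.
#' @return Numeric vector of `n` angles in `(-pi, pi]`.
#' @export
rwrappedcauchy <- function(n, gamma, kappa) {
  check_wc_params(gamma, kappa)
  if (n < 1) abort("`n` must be at least 1.")
  if (kappa == 0) {
    return(wrap_to_pi(runif(n, -pi, pi)))
  }
  scale <- -log(kappa)
  wrap_to_pi(gamma + scale * tan(pi * (runif(n) - 0.5)))
}

check_step_params <- function(family, shape = NULL, scale = NULL,
                              rate = NULL) {
  family <- match.arg(family, c("weibull", "exponential"))
  pos_scalar <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      abort(sprintf("`%s` must be a positive finite scalar.", nm))
    }
  }
  if (family == "weibull") {
    pos_scalar(shape, "shape")
    pos_scalar(scale, "scale")
  } else {
    pos_scalar(rate, "rate")
  }
  family
}

#' Step-length log-density
#'
#' Log-density of a step length under the Weibull (shape--scale
#' parameterization, as in [stats::dweibull()]) or exponential (rate)
#' family. Step lengths are in metres throughout the package.
#'
#' @param s Positive numeric vector of step lengths (metres).
#' @param family `"weibull"` or `"exponential"`.
#' @param shape,scale Weibull shape \eqn{\alpha > 0} and scale
#'   \eqn{\beta > 0} (used when `family = "weibull"`).
#' @param rate Exponential rate \eqn{\lambda > 0} (used when
#'   `family = "exponential"`).
#' @return Numeric vector of log-densities.
#' @examples
#' step_logpdf(1, family = "exponential", rate = 1)  # -1
#' @export
step_logpdf <- function(s, family = c("weibull", "exponential"),
                        shape = NULL, scale = NULL, rate = NULL) {
  family <- check_step_params(family, shape, scale, rate)
  if (any(!is.finite(s)) || any(s <= 0)) {
    abort("step lengths must be positive and finite; clean zero-length steps upstream.")
  }
  if (family == "weibull") {
    dweibull(s, shape = shape, scale = scale, log = TRUE)
  } else {
    dexp(s, rate = rate, log = TRUE)
  }
}

#' Sample step lengths
#'
#' @inheritParams step_logpdf
#' @param n Number of draws.
#' @return Numeric vector of `n` positive step lengths (metres).
#' @export
rstep <- function(n, family = c("weibull", "exponential"),
                  shape = NULL, scale = NULL, rate = NULL) {
  family <- check_step_params(family, shape, scale, rate)
  if (family == "weibull") {
    stats::rweibull(n, shape = shape, scale = scale)
  } else {
    stats::rexp(n, rate = rate)
  }
}
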