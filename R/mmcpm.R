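#' Prior configuration for the movement-metric model
#'
#' @param spike_weight Prior probability of the spike (`tau = 0`).
#' @param beta_max Upper bound of the uniform prior on the Weibull scale
#'   (metres). The canonical bound of 50 presumes coarser length units than
#'   the metres used throughout this package; the default of 500 m keeps
#'   the prior diffuse for sub-hourly ungulate step lengths and is
#'   configurable.
#' @param alpha_shape,alpha_rate Shape and rate of the Gamma prior on the
#'   Weibull shape parameter (default `Gamma(0.001, 0.001)`).
#' @param lambda_shape,lambda_rate Shape and rate of the Gamma prior on the
#'   exponential rate (default `Gamma(0.001, 0.001)`).
#' @return A list of class `mmcpm_priors`. Turning-angle priors are fixed:
#'   location `gamma ~ U(-pi, pi)`, concentration `kappa ~ U(0, 1)`.
#' @export
mmcpm_priors <- function(spike_weight = 0.5, beta_max = 500,
                         alpha_shape = 0.001, alpha_rate = 0.001,
                         lambda_shape = 0.001, lambda_rate = 0.001) {
  stopifnot(spike_weight > 0, spike_weight < 1, beta_max > 0,
            alpha_shape > 0, alpha_rate > 0, lambda_shape > 0,
            lambda_rate > 0)
  structure(list(spike_weight = spike_weight, beta_max = beta_max,
                 alpha_shape = alpha_shape, alpha_rate = alpha_rate,
                 lambda_shape = lambda_shape, lambda_rate = lambda_rate),
            class = "mmcpm_priors")
}

# Validate a metrics tibble from compute_metrics(); returns it with
# contiguous t and positive steps checked.
validate_metrics <- function(metrics) {
  req <- c("t", "step_m", "angle_rad")
  miss <- setdiff(req, names(metrics))
  if (length(miss) > 0) {
    abort(sprintf("metrics tibble is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  metrics <- dplyr::arrange(as_tibble(metrics), .data$t)
  if (!all(diff(metrics$t) == 1)) abort("metric time indices must be contiguous.")
  if (any(is.na(metrics$step_m)) || any(metrics$step_m <= 0)) {
    abort("step lengths must be positive; drop zero-length steps upstream.")
  }
  metrics
}

# per-term state-wise log-densities; rows = metric terms t = 2..T
mmcpm_term_matrix <- function(metrics, pars, family) {
  st <- metrics$step_m
  an <- metrics$angle_rad
  one_state <- function(i) {
    v <- if (family == "weibull") {
      dweibull(st, shape = pars$alpha[i], scale = pars$beta[i], log = TRUE)
    } else {
      dexp(st, rate = pars$lambda[i], log = TRUE)
    }
    ok <- !is.na(an)
    v[ok] <- v[ok] + dwrappedcauchy(an[ok], pars$gamma[i], pars$kappa[i],
                                    log = TRUE)
    v
  }
  cbind(one_state(1), one_state(2))
}

#' Log-likelihood of the movement-metric change-point model
#'
#' Joint likelihood of turning angles (wrapped Cauchy) and step lengths
#' (Weibull or exponential), each term assigned to state 1 (`t < tau`) or
#' state 2 (`t >= tau`) by its time index; both metric streams share the
#' single change point `tau` (`tau = 0`: all state 1). Missing angles
#' (zero-length step neighbourhoods, the final index) are dropped from the
#' product.
#'
#' @param metrics Metrics tibble from [compute_metrics()] (columns `t`,
#'   `step_m`, `angle_rad`).
#' @param pars Named list with per-state parameters: `gamma` (length 2),
#'   `kappa` (length 2), and `alpha`/`beta` (Weibull) or `lambda`
#'   (exponential), each length 2.
#' @param family `"weibull"` or `"exponential"`.
#' @param tau Change point: 0 or a metric time index present in
#'   `metrics$t` (or `max(t) + 1` for "change after the last term").
#' @return Scalar log-likelihood.
#' @export
mmcpm_loglik <- function(metrics, pars, family = c("weibull", "exponential"),
                         tau) {
  family <- match.arg(family)
  metrics <- validate_metrics(metrics)
  T <- max(metrics$t)
  if (!(tau == 0 || (tau >= 2 && tau <= T))) {
    abort("`tau` must be 0 or an index in 2..T.")
  }
  lm <- mmcpm_term_matrix(metrics, pars, family)
  state <- if (tau == 0) rep(1L, nrow(lm)) else ifelse(metrics$t < tau, 1L, 2L)
  sum(lm[cbind(seq_len(nrow(lm)), state)])
}

#' Full conditional of the change point under the MMCPM
#'
#' @inheritParams mmcpm_loglik
#' @param priors An [mmcpm_priors()] object (only `spike_weight` is used).
#' @return Named probability vector over `{0} \eqn{\cup} {2..T}`.
#' @export
mmcpm_tau_conditional <- function(metrics, pars,
                                  family = c("weibull", "exponential"),
                                  priors = mmcpm_priors()) {
  family <- match.arg(family)
  metrics <- validate_metrics(metrics)
  lm <- mmcpm_term_matrix(metrics, pars, family)
  tau_conditional_from_terms(lm, priors$spike_weight)
}

#' Fit the movement-metric change-point model
#'
#' Metropolis-within-Gibbs sampler sharing the spike-and-slab change point
#' across the angle and step streams. `tau` is drawn exactly from its
#' categorical full conditional via prefix/suffix sums of the joint
#' per-term log-densities. The exponential rate has a conjugate Gamma full
#' conditional; `gamma` (wrapped random walk), `kappa`, the Weibull shape
#' (log scale) and scale are updated by adaptive random-walk Metropolis
#' respecting their prior supports. While a state is empty (e.g. state 2
#' when `tau = 0`) its parameters are updated by the same kernels
#' targeting the prior, which preserves the exact posterior and lets the
#' chain re-enter the slab.
#'
#' @param metrics Metrics tibble from [compute_metrics()]. Rows with
#'   missing angles are retained (their angle term is dropped); rows with
#'   non-positive steps must be cleaned beforehand.
#' @param family Step-length family: `"weibull"` (flexible; can chase
#'   isolated large steps) or `"exponential"` (less flexible; preferable
#'   when rare large steps would otherwise masquerade as the change).
#' @param priors An [mmcpm_priors()] object.
#' @param mcmc An [mcmc_config()] object.
#' @param seed Optional integer seed.
#' @param init Optional named list of initial values (`gamma`, `kappa`,
#'   `alpha`, `beta`, `lambda` each length 2, and `tau`).
#' @return An object of class `mmcpm_fit` (and `cpt_fit`).
#' @export
fit_mmcpm <- function(metrics, family = c("weibull", "exponential"),
                      priors = mmcpm_priors(), mcmc = mcmc_config("desk"),
                      seed = NULL, init = NULL) {
  family <- match.arg(family)
  metrics <- validate_metrics(metrics)
  if (nrow(metrics) < 4) abort("need at least 4 usable metric terms.")
  T <- max(metrics$t)
  if (!is.null(seed)) set.seed(seed)

  if (is.null(init)) {
    h <- floor(nrow(metrics) / 2)
    s1 <- metrics$step_m[seq_len(h)]
    s2 <- metrics$step_m[(h + 1):nrow(metrics)]
    a1 <- metrics$angle_rad[seq_len(h)]
    a2 <- metrics$angle_rad[(h + 1):nrow(metrics)]
    circ <- function(a) {
      a <- a[!is.na(a)]
      if (length(a) == 0) return(list(mean = 0, R = 0.1))
      C <- mean(cos(a)); S <- mean(sin(a))
      list(mean = atan2(S, C), R = min(sqrt(C^2 + S^2), 0.95))
    }
    c1 <- circ(a1); c2 <- circ(a2)
    init <- list(gamma = c(c1$mean, c2$mean),
                 kappa = pmax(c(c1$R, c2$R), 0.01),
                 alpha = c(1, 1),
                 beta = pmin(c(mean(s1), mean(s2)), priors$beta_max * 0.99),
                 lambda = c(1 / mean(s1), 1 / mean(s2)),
                 tau = max(2L, floor(T / 2)))
  }
  iv <- c(init$gamma[1], init$kappa[1], init$gamma[2], init$kappa[2],
          init$alpha[1], init$beta[1], init$alpha[2], init$beta[2],
          init$lambda[1], init$lambda[2], init$tau)

  res <- mmcpm_mcmc_cpp(metrics$step_m, metrics$angle_rad,
                        if (family == "weibull") 0L else 1L,
                        priors$spike_weight, priors$beta_max,
                        priors$alpha_shape, priors$alpha_rate,
                        priors$lambda_shape, priors$lambda_rate,
                        mcmc$n_iter, mcmc$n_burn, mcmc$thin, iv,
                        TRUE, -1L, FALSE)
  draws <- as_tibble(as.data.frame(res$draws))
  draws$tau <- as.integer(draws$tau)
  keep <- if (family == "weibull") {
    c("gamma1", "kappa1", "gamma2", "kappa2", "alpha1", "beta1", "alpha2",
      "beta2", "tau", "loglik")
  } else {
    c("gamma1", "kappa1", "gamma2", "kappa2", "lambda1", "lambda2", "tau",
      "loglik")
  }
  draws <- draws[, keep]
  structure(list(draws = draws, metrics = metrics, family = family,
                 priors = priors, mcmc = mcmc, T = T, model = "mmcpm",
                 seed = seed),
            class = c("mmcpm_fit", "cpt_fit"))
}
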