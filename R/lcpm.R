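#' Prior configuration for the location-based model
#'
#' @param spike_weight Prior probability `w` of the spike (`tau = 0`, no
#'   change). The slab spreads `1 - w` uniformly over candidate change
#'   times `{2..T}`. Default 0.5.
#' @param sigma_max Upper bound of the uniform prior on the observation
#'   noise SD `sigma` (metres). Default `1e7`.
#' @param mu_sd Prior standard deviation (metres) of the zero-mean normal
#'   prior on each centroid coordinate. Default 5000 m: weakly informative
#'   at landscape scale once tracks are mean-centered.
#' @param rho_min,rho_max Bounds of the uniform prior on the autocorrelation
#'   `rho` of the AR(1) attractor process. Defaults 0 and 0.8: positive
#'   autocorrelation while retaining attraction to a geographic centroid.
#' @return A list of class `lcpm_priors`.
#' @export
lcpm_priors <- function(spike_weight = 0.5, sigma_max = 1e7, mu_sd = 5000,
                        rho_min = 0, rho_max = 0.8) {
  stopifnot(spike_weight > 0, spike_weight < 1, sigma_max > 0, mu_sd > 0,
            rho_min >= -1, rho_max <= 1, rho_min < rho_max)
  structure(list(spike_weight = spike_weight, sigma_max = sigma_max,
                 mu_sd = mu_sd, rho_min = rho_min, rho_max = rho_max),
            class = "lcpm_priors")
}

#' MCMC schedule
#'
#' Two presets: `"paper"` (200,000 iterations after a 100,000-iteration
#' burn-in, thinned to every 4th draw; long refits use 500,000/250,000) for
#' production runs, and `"desk"` (20,000/10,000, thinned by 2) for
#' interactive work and tests.
#'
#' @param profile `"desk"` or `"paper"`, or `NULL` when giving the schedule
#'   explicitly.
#' @param n_iter Post-burn-in iterations.
#' @param n_burn Burn-in iterations (adaptation of proposal scales happens
#'   here only).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param refit_mult Multiplier applied to `n_iter`/`n_burn` when a
#'   convergence-triggered refit is required (2.5 reproduces
#'   500k/250k from 200k/100k).
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(profile = c("desk", "paper"), n_iter = NULL,
                        n_burn = NULL, thin = NULL, refit_mult = 2.5) {
  if (is.null(n_iter)) {
    profile <- match.arg(profile)
    cfg <- switch(profile,
                  desk  = list(n_iter = 20000L, n_burn = 10000L, thin = 2L),
                  paper = list(n_iter = 200000L, n_burn = 100000L, thin = 4L))
  } else {
    cfg <- list(n_iter = as.integer(n_iter),
                n_burn = as.integer(n_burn %||% n_iter %/% 2),
                thin = as.integer(thin %||% 1L))
    profile <- "custom"
  }
  stopifnot(cfg$n_iter > 0, cfg$n_burn >= 0, cfg$thin >= 1)
  structure(c(cfg, list(profile = profile, refit_mult = refit_mult)),
            class = "mcmc_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-term state-wise log-densities for t = 2..T; rows t-2, cols state 1/2
lcpm_term_matrix <- function(track, mu1, mu2, sigma, rho) {
  xy <- cbind(track$x, track$y)
  T <- nrow(xy)
  prev <- xy[-T, , drop = FALSE]
  cur <- xy[-1, , drop = FALSE]
  term <- function(mu) {
    m <- rho * prev + (1 - rho) * matrix(mu, T - 1, 2, byrow = TRUE)
    dnorm(cur[, 1], m[, 1], sigma, log = TRUE) +
      dnorm(cur[, 2], m[, 2], sigma, log = TRUE)
  }
  cbind(term(mu1), term(mu2))
}

#' Log-likelihood of the location-based change-point model
#'
#' Positions follow a two-state AR(1) attractor process:
#' \deqn{y_t \sim N(\rho y_{t-1} + (1-\rho)\mu_i, \sigma^2 I)} with state
#' `i = 1` for `t < tau` and `i = 2` for `t >= tau` (`tau = 0`: state 1
#' throughout). The likelihood conditions on the first location; there is
#' no density term for `t = 1`.
#'
#' @param track Single-individual, mean-centered, regular track tibble.
#' @param mu1,mu2 State centroids, numeric length-2 (metres).
#' @param sigma Observation noise SD (metres), positive.
#' @param rho AR(1) autocorrelation.
#' @param tau Change point: 0 (no change) or an index in `2..T`.
#' @return Scalar log-likelihood.
#' @export
lcpm_loglik <- function(track, mu1, mu2, sigma, rho, tau) {
  track <- validate_track(track)
  T <- nrow(track)
  if (sigma <= 0) abort("`sigma` must be positive.")
  if (!(tau == 0 || (tau >= 2 && tau <= T))) {
    abort("`tau` must be 0 or an index in 2..T.")
  }
  lm <- lcpm_term_matrix(track, mu1, mu2, sigma, rho)
  state <- if (tau == 0) rep(1L, T - 1) else ifelse(2:T < tau, 1L, 2L)
  sum(lm[cbind(seq_len(T - 1), state)])
}

# shared spike-and-slab categorical full conditional given per-term
# state-wise log-densities (rows = terms t = 2..T)
tau_conditional_from_terms <- function(lm, spike_weight) {
  n <- nrow(lm)
  T <- n + 1
  pre <- c(0, cumsum(lm[, 1]))            # pre[k+1] = sum of state-1 terms 1..k
  suf <- rev(c(0, cumsum(rev(lm[, 2]))))  # suf[j] = sum of state-2 terms j..n
  lw <- c(log(spike_weight) + pre[n + 1],
          log1p(-spike_weight) - log(T - 1) + pre[seq_len(n)] + suf[seq_len(n)])
  if (all(!is.finite(lw))) abort("change-point full conditional is degenerate (all -Inf).")
  p <- exp(lw - max(lw))
  setNames(p / sum(p), c(0, 2:T))
}

#' Full conditional of the change point under the LCPM
#'
#' Probability vector of `tau` over `{0} \eqn{\cup} `{2..T}` given all
#' continuous parameters, computed in O(T) via prefix/suffix sums of the
#' per-term state-wise log-densities and stabilized by max-subtraction.
#'
#' @inheritParams lcpm_loglik
#' @param priors An [lcpm_priors()] object (only `spike_weight` is used).
#' @return Named numeric vector of probabilities (names `"0"`, `"2"`, ...,
#'   `"T"`) summing to 1.
#' @export
lcpm_tau_conditional <- function(track, mu1, mu2, sigma, rho,
                                 priors = lcpm_priors()) {
  track <- validate_track(track)
  lm <- lcpm_term_matrix(track, mu1, mu2, sigma, rho)
  tau_conditional_from_terms(lm, priors$spike_weight)
}

#' Fit the location-based change-point model
#'
#' Metropolis-within-Gibbs sampler: exact categorical draw of `tau` from
#' its spike-and-slab full conditional each sweep, conjugate normal draws
#' for the two centroids (the prior draw when a state is empty), and
#' adaptive random-walk Metropolis for `sigma` (log scale) and `rho`
#' (logit scale on its prior support), with adaptation during burn-in only.
#' A single chain is run; with symmetric priors the two state labels are
#' only identified through time order, and a single chain avoids having to
#' reconcile label switching across chains.
#'
#' @param track Single-individual, regular track; it is mean-centered
#'   internally if not already centered.
#' @param priors An [lcpm_priors()] object.
#' @param mcmc An [mcmc_config()] object.
#' @param seed Optional integer seed (applied via [set.seed()]).
#' @param init Optional named list of initial values
#'   (`mu1`, `mu2`, `sigma`, `rho`, `tau`); defaults are moment-based.
#' @return An object of class `lcpm_fit` with elements `draws` (tibble of
#'   thinned posterior draws), `track`, `priors`, `mcmc` and `T`.
#' @export
fit_lcpm <- function(track, priors = lcpm_priors(), mcmc = mcmc_config("desk"),
                     seed = NULL, init = NULL) {
  track <- validate_track(track)
  T <- nrow(track)
  if (T < 4) abort("need at least 4 locations to fit the LCPM.")
  track_interval(track)
  if (abs(mean(track$x)) > 1e-6 || abs(mean(track$y)) > 1e-6) {
    track <- center_locations(track)
  }
  if (!is.null(seed)) set.seed(seed)

  if (is.null(init)) {
    h <- floor(T / 2)
    s0 <- stats::sd(c(diff(track$x), diff(track$y)))
    init <- list(mu1 = c(mean(track$x[1:h]), mean(track$y[1:h])),
                 mu2 = c(mean(track$x[(h + 1):T]), mean(track$y[(h + 1):T])),
                 sigma = max(s0, 1e-3), rho = mean(c(priors$rho_min, priors$rho_max)),
                 tau = max(2L, h))
  }
  iv <- c(init$mu1, init$mu2, init$sigma, init$rho, init$tau)

  res <- lcpm_mcmc_cpp(cbind(track$x, track$y), priors$spike_weight,
                       priors$sigma_max, priors$mu_sd, priors$rho_min,
                       priors$rho_max, mcmc$n_iter, mcmc$n_burn, mcmc$thin,
                       iv, TRUE, -1L, FALSE)
  draws <- as_tibble(as.data.frame(res$draws))
  draws$tau <- as.integer(draws$tau)
  structure(list(draws = draws, track = track, priors = priors, mcmc = mcmc,
                 T = T, model = "lcpm", seed = seed),
            class = c("lcpm_fit", "cpt_fit"))
}

#' @export
print.cpt_fit <- function(x, ...) {
  dc <- detect_change(x$draws$tau)
  cat(sprintf("<%s> %d locations, %d posterior draws\n", toupper(x$model),
              x$T, nrow(x$draws)))
  cat(sprintf("  change point: %s (posterior mode %d; P[tau = 0] = %.3f)\n",
              if (dc$detected) "detected" else "not detected",
              dc$mode, mean(x$draws$tau == 0)))
  invisible(x)
}
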