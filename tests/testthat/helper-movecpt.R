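# Shared fixtures and small independent oracles for the test suite.

# tiny MCMC schedules for unit tests (the "desk" profile is used for the
# replicate-level acceptance runs)
tiny_mcmc <- movecpt::mcmc_config(n_iter = 1000, n_burn = 500, thin = 1)
short_mcmc <- movecpt::mcmc_config(n_iter = 4000, n_burn = 2000, thin = 2)

# deterministic toy track: a gentle arc, T points, 15-min interval
toy_track <- function(T = 10, seed = 7, sd = 5) {
  set.seed(seed)
  th <- seq(0, pi / 3, length.out = T)
  tibble::tibble(
    id = "toy",
    time = as.POSIXct("2020-05-01", tz = "UTC") + (seq_len(T) - 1) * 900,
    x = 100 * cos(th) + rnorm(T, 0, sd),
    y = 100 * sin(th) + rnorm(T, 0, sd)
  )
}

# naive O(T^2) enumeration of the spike-and-slab tau full conditional from
# any loglik function loglik(tau); independent of the prefix-sum path
naive_tau_conditional <- function(loglik, T, w) {
  taus <- c(0, 2:T)
  lp <- vapply(taus, function(tau) {
    pr <- if (tau == 0) log(w) else log(1 - w) - log(T - 1)
    pr + loglik(tau)
  }, numeric(1))
  p <- exp(lp - max(lp))
  stats::setNames(p / sum(p), taus)
}

# Kuiper one-sample test (circular-invariant two-sided EDF test).
# Returns the asymptotic p-value for the null "u are iid U(0,1)".
kuiper_p <- function(u) {
  n <- length(u)
  u <- sort(u)
  i <- seq_len(n)
  V <- max(i / n - u) + max(u - (i - 1) / n)
  lam <- (sqrt(n) + 0.155 + 0.24 / sqrt(n)) * V
  j <- 1:100
  p <- 2 * sum((4 * j^2 * lam^2 - 1) * exp(-2 * j^2 * lam^2))
  min(max(p, 0), 1)
}

# numeric CDF of the wrapped Cauchy on (-pi, pi] via a fine trapezoid grid
wc_cdf <- function(a, gamma, kappa, m = 8192) {
  g <- seq(-pi, pi, length.out = m + 1)
  d <- movecpt::dwrappedcauchy(g, gamma, kappa)
  cdf <- c(0, cumsum((d[-1] + d[-(m + 1)]) / 2 * diff(g)))
  stats::approx(g, cdf / cdf[m + 1], xout = a)$y
}

# chi-square goodness-of-fit of sampled tau draws against an enumerated
# conditional, pooling low-probability cells
tau_gof_p <- function(draws, probs) {
  vals <- as.integer(names(probs))
  obs <- vapply(vals, function(v) sum(draws == v), integer(1))
  keep <- probs * length(draws) >= 5
  obs2 <- c(obs[keep], sum(obs[!keep]))
  exp2 <- c(probs[keep], sum(probs[!keep])) * length(draws)
  nz <- exp2 > 0
  stat <- sum((obs2[nz] - exp2[nz])^2 / exp2[nz])
  stats::pchisq(stat, df = sum(nz) - 1, lower.tail = FALSE)
}

# interior-truth generating values for parameter-recovery runs (kept away
# from prior boundaries, where nominal CI coverage is ill-defined)
recovery_lcpm <- list(shift = 1026, sigma = 150, rho = 0.6)
recovery_mm <- list(
  pre = list(gamma = 0.5, kappa = 0.3, alpha = 1.3, beta = 120, lambda = 1 / 110),
  post = list(gamma = 2.0, kappa = 0.7, alpha = 1.8, beta = 50, lambda = 1 / 45)
)
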