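# small deterministic metrics fixture: 6 usable terms (t = 2..7)
toy_metrics <- function(seed = 13, n = 6) {
  set.seed(seed)
  tibble::tibble(
    id = "toy", t = seq_len(n) + 1L,
    time = as.POSIXct("2020-05-01", tz = "UTC") + seq_len(n) * 900,
    step_m = round(rweibull(n, 1.3, 100), 2),
    angle_rad = c(round(runif(n - 1, -pi + 0.01, pi), 3), NA)
  )
}

toy_pars <- list(gamma = c(0.2, -2.5), kappa = c(0.3, 0.8),
                 alpha = c(1.2, 1.9), beta = c(110, 40),
                 lambda = c(1 / 95, 1 / 35))

test_that("MMCPM log-likelihood matches a hand-summed per-term oracle", {
  m <- toy_metrics()
  for (family in c("weibull", "exponential")) {
    for (tau in c(0, 2:7)) {
      oracle <- 0
      for (i in seq_len(nrow(m))) {
        st <- if (tau != 0 && m$t[i] >= tau) 2 else 1
        oracle <- oracle + if (family == "weibull") {
          dweibull(m$step_m[i], toy_pars$alpha[st], toy_pars$beta[st], log = TRUE)
        } else {
          dexp(m$step_m[i], toy_pars$lambda[st], log = TRUE)
        }
        if (!is.na(m$angle_rad[i])) {
          oracle <- oracle + dwrappedcauchy(m$angle_rad[i],
                                            toy_pars$gamma[st],
                                            toy_pars$kappa[st], log = TRUE)
        }
      }
      expect_equal(mmcpm_loglik(m, toy_pars, family, tau), oracle,
                   tolerance = 1e-10)
    }
  }
})

test_that("MMCPM log-likelihood decomposes into angle and step streams", {
  m <- toy_metrics()
  tau <- 4
  joint <- mmcpm_loglik(m, toy_pars, "weibull", tau)
  st <- ifelse(m$t < tau, 1, 2)
  steps_only <- sum(dweibull(m$step_m, toy_pars$alpha[st], toy_pars$beta[st],
                             log = TRUE))
  ok <- !is.na(m$angle_rad)
  angles_only <- sum(vapply(which(ok), function(i)
    dwrappedcauchy(m$angle_rad[i], toy_pars$gamma[st[i]], toy_pars$kappa[st[i]],
                   log = TRUE), numeric(1)))
  expect_equal(joint, steps_only + angles_only, tolerance = 1e-10)
})

test_that("MMCPM reductions: identical states and uniform angles", {
  m <- toy_metrics()
  same <- list(gamma = c(0.2, 0.2), kappa = c(0.3, 0.3),
               alpha = c(1.2, 1.2), beta = c(110, 110),
               lambda = c(0.01, 0.01))
  vals <- vapply(c(0, 2:7), function(tau)
    mmcpm_loglik(m, same, "weibull", tau), numeric(1))
  expect_lt(diff(range(vals)), 1e-10)

  # kappa = 0 in both states: angle contribution is n_angles * log(1/(2pi))
  unif <- modifyList(same, list(kappa = c(0, 0)))
  n_ang <- sum(!is.na(m$angle_rad))
  st <- ifelse(m$t < 5, 1, 2)
  steps_only <- sum(dweibull(m$step_m, 1.2, 110, log = TRUE))
  expect_equal(mmcpm_loglik(m, unif, "weibull", 5),
               steps_only + n_ang * log(1 / (2 * pi)), tolerance = 1e-10)

  bad <- m; bad$step_m[2] <- 0
  expect_error(mmcpm_loglik(bad, same, "weibull", 0), "positive")
})

test_that("MMCPM tau full conditional matches naive enumeration", {
  m <- toy_metrics(seed = 14, n = 9)  # t = 2..10, T = 10
  pr <- mmcpm_priors(spike_weight = 0.4)
  for (family in c("weibull", "exponential")) {
    p <- mmcpm_tau_conditional(m, toy_pars, family, pr)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    naive <- naive_tau_conditional(function(tau)
      mmcpm_loglik(m, toy_pars, family, tau), 10, 0.4)
    expect_equal(p, naive, tolerance = 1e-10)
  }
})

test_that("clamped tau chain matches the enumerated conditional (chi-square)", {
  m <- toy_metrics(seed = 15, n = 9)
  probs <- mmcpm_tau_conditional(m, toy_pars, "weibull", mmcpm_priors())
  set.seed(101)
  iv <- c(toy_pars$gamma[1], toy_pars$kappa[1], toy_pars$gamma[2],
          toy_pars$kappa[2], toy_pars$alpha[1], toy_pars$beta[1],
          toy_pars$alpha[2], toy_pars$beta[2], toy_pars$lambda, 2)
  res <- movecpt:::mmcpm_mcmc_cpp(m$step_m, m$angle_rad, 0L, 0.5, 500,
                                  0.001, 0.001, 0.001, 0.001,
                                  5000L, 0L, 1L, iv, FALSE, -1L, FALSE)
  draws <- as.integer(res$draws[, "tau"])
  expect_gt(tau_gof_p(draws, probs), 0.001)
})

test_that("exponential rate with clamped tau matches the conjugate posterior", {
  sim <- simulate_mm_track("both", family = "exponential",
                           pre_hours = 12, post_hours = 12, seed = 77)
  m <- sim$metrics[sim$metrics$step_m > 0, ]
  tau <- sim$tau_true
  set.seed(78)
  iv <- c(0, 0.2, 0, 0.2, 1, 100, 1, 100, 0.01, 0.01, tau)
  res <- movecpt:::mmcpm_mcmc_cpp(m$step_m, m$angle_rad, 1L, 0.5, 500,
                                  0.001, 0.001, 0.001, 0.001,
                                  20000L, 2000L, 2L, iv, TRUE, tau, FALSE)
  d <- as.data.frame(res$draws)
  s1 <- m$step_m[m$t < tau]
  sh <- 0.001 + length(s1); ra <- 0.001 + sum(s1)
  n_draw <- nrow(d)
  # posterior mean and SD of Gamma(sh, ra), tested within 3 MC SE
  ess <- n_draw  # conjugate draws given tau are iid here
  expect_lt(abs(mean(d$lambda1) - sh / ra), 3 * sqrt(sh) / ra / sqrt(ess))
  expect_equal(sd(d$lambda1), sqrt(sh) / ra, tolerance = 0.1)

  s2 <- m$step_m[m$t >= tau]
  sh2 <- 0.001 + length(s2); ra2 <- 0.001 + sum(s2)
  expect_lt(abs(mean(d$lambda2) - sh2 / ra2), 3 * sqrt(sh2) / ra2 / sqrt(ess))
})

test_that("prior-only run reproduces the MMCPM priors", {
  m <- toy_metrics(seed = 16, n = 9)
  set.seed(102)
  iv <- c(0, 0.5, 0, 0.5, 1, 100, 1, 100, 0.01, 0.01, 0)
  res <- movecpt:::mmcpm_mcmc_cpp(m$step_m, m$angle_rad, 0L, 0.7, 300,
                                  0.001, 0.001, 0.001, 0.001,
                                  20000L, 0L, 1L, iv, TRUE, -1L, TRUE)
  d <- as.data.frame(res$draws)
  expect_equal(mean(d$tau == 0), 0.7, tolerance = 0.015)
  expect_true(all(d$gamma1 >= -pi & d$gamma1 <= pi))
  expect_equal(mean(d$kappa2), 0.5, tolerance = 0.02)    # U(0, 1)
  expect_equal(mean(d$beta1), 150, tolerance = 0.03)     # U(0, 300)
})

test_that("no-change data land in the spike and the relabeled twin tau = 2
           keeps its prior-odds posterior mass", {
  spikes <- 0
  ratios <- c()
  for (i in 1:6) {
    sim <- simulate_mm_track("none", pre_hours = 24, post_hours = 24,
                             seed = 500 + i)
    fit <- fit_mmcpm(sim$metrics[sim$metrics$step_m > 0, ], "weibull",
                     mcmc = short_mcmc, seed = 600 + i)
    dc <- detect_change(fit$draws$tau)
    spikes <- spikes + !dc$detected
    p0 <- mean(fit$draws$tau == 0)
    if (p0 > 0.5) ratios <- c(ratios, mean(fit$draws$tau == 2) / p0)
  }
  expect_gte(spikes, 5)  # large majority undetected
  # exact relabeling identity: P(tau = 2) / P(tau = 0) equals the prior
  # odds (1 - w) / ((T - 1) w); pooled over chains to beat MC noise
  T <- 193
  expect_equal(mean(ratios), (1 - 0.5) / ((T - 1) * 0.5), tolerance = 0.5)
})

test_that("fit_mmcpm detects a change in both metrics on simulated data", {
  sim <- simulate_mm_track("both", seed = 103)
  m <- sim$metrics
  fit <- fit_mmcpm(m, "weibull", mcmc = short_mcmc, seed = 104)
  g <- glance(fit)
  expect_true(g$detected)
  expect_lt(abs(g$tau_mode - sim$tau_true), 8)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "beta1"], 120, tolerance = 0.15)
  expect_equal(td$estimate[td$term == "beta2"], 35, tolerance = 0.15)
  expect_equal(td$estimate[td$term == "kappa2"], 0.7, tolerance = 0.1)
})
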