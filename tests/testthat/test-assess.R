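test_that("detection rule uses the posterior mode with a conservative tie rule", {
  expect_equal(detect_change(c(0, 0, 0, 7)),
               tibble::tibble(detected = FALSE, mode = 0L))
  expect_equal(detect_change(c(5, 5, 0)),
               tibble::tibble(detected = TRUE, mode = 5L))
  expect_equal(detect_change(c(0, 0, 5, 5)),
               tibble::tibble(detected = FALSE, mode = 0L))
  expect_error(detect_change(integer(0)))
})

test_that("success levels follow the a-priori credible-interval definitions", {
  # all draws at the truth: Level 1, zero width
  r <- classify_success(rep(100L, 50), 100, 15)
  expect_equal(as.character(r$success_level), "1")
  expect_equal(r$width95_h, 0)

  # diffuse posterior over 16 days of hourly fixes (truth near the start):
  # its median sits days away from the event, so classification fails
  set.seed(1)
  diffuse <- sample(2:385, 2000, replace = TRUE)
  r2 <- classify_success(diffuse, 50, 60)
  expect_equal(as.character(r2$success_level), "unsuccessful")
  expect_gt(r2$width95_h, 12)

  # 95% CI ~ [-8, +8] h but 50% CI within [-2, +2] h: Level 2
  # hourly data: draws in index units around truth 500
  lvl2 <- c(rep(500L, 800), rep(498L, 100), rep(502L, 100),
            rep(492L, 40), rep(508L, 40))
  q <- quantile((lvl2 - 500) * 60 / 60, c(0.025, 0.975))
  expect_true(q[1] <= -6 || q[2] >= 6)  # sanity: 95% CI escapes the window
  r3 <- classify_success(lvl2, 500, 60)
  expect_equal(as.character(r3$success_level), "2")

  # median inside, 50% CI outside: Level 3
  lvl3 <- c(rep(500L, 300), rep(520L, 250), rep(480L, 220), rep(450L, 230))
  r4 <- classify_success(lvl3, 500, 60)
  expect_equal(as.character(r4$success_level), "3")

  # undetected: level "none"
  r5 <- classify_success(c(rep(0L, 10), 5L), 5, 15)
  expect_equal(as.character(r5$success_level), "none")
  expect_false(r5$detected)
})

test_that("levels are nested and shift-invariant", {
  set.seed(2)
  for (i in 1:25) {
    draws <- pmax(2L, as.integer(round(rnorm(400, 200, runif(1, 1, 60)))))
    r <- classify_success(draws, 200L, 15)
    q <- quantile((draws - 200) * 15 / 60, c(0.025, 0.25, 0.5, 0.75, 0.975))
    in6 <- function(lo, hi) lo >= -6 && hi <= 6
    lev <- as.character(r$success_level)
    if (lev == "1") {
      expect_true(in6(q[2], q[4]))  # Level 1 implies the Level 2 condition
      expect_true(in6(q[3], q[3]))  # ... and the Level 3 condition
    }
    if (lev %in% c("1", "2")) expect_true(in6(q[3], q[3]))
    # common time shift of draws and truth leaves the classification alone
    r_sh <- classify_success(draws + 57L, 257L, 15)
    expect_equal(as.character(r_sh$success_level), lev)
    expect_equal(r_sh$width95_h, r$width95_h)
  }
})

test_that("Geweke diagnostic matches coda and calibrates near its nominal rate", {
  skip_if_not_installed("coda")
  set.seed(3)
  for (i in 1:5) {
    x <- as.numeric(arima.sim(list(ar = 0.6), 2000))
    expect_lt(abs(geweke_z(x) - unname(coda::geweke.diag(coda::mcmc(x))$z)),
              0.1)
  }
  # null calibration: iid chains should be flagged at roughly the N(0,1)
  # rate, i.e. |z| <= 2 about 95% of the time
  set.seed(4)
  ok <- mean(replicate(400, abs(geweke_z(rnorm(1000))) <= 2))
  expect_gt(ok, 0.92)
  expect_lt(ok, 0.99)
  # a trending chain is flagged as non-converged
  expect_gt(abs(geweke_z(seq(0, 1, length.out = 1000) +
                           rnorm(1000, 0, 0.05))), 2)
  # constant chain: degenerate, NA
  expect_true(is.na(geweke_z(rep(1, 500))))
  expect_error(geweke_z(rnorm(50)), "at least 100")
})

test_that("convergence check applies |z| <= 2 to every continuous chain", {
  set.seed(5)
  mkfit <- function(...) {
    structure(list(draws = tibble::tibble(...), T = 10, model = "lcpm"),
              class = c("lcpm_fit", "cpt_fit"))
  }
  good <- mkfit(sigma = rnorm(1000), rho = rnorm(1000),
                tau = rep(3L, 1000), loglik = rnorm(1000))
  cc <- check_convergence(good)
  zs <- c(geweke_z(good$draws$sigma), geweke_z(good$draws$rho))
  expect_equal(cc$converged, all(abs(zs) <= 2))
  expect_equal(cc$max_abs_z, max(abs(zs)))
  # tau and loglik are excluded: a trending tau chain alone does not flag
  trend <- mkfit(sigma = rnorm(1000), rho = rnorm(1000),
                 tau = as.integer(seq(2, 300, length.out = 1000)),
                 loglik = seq(0, 1, length.out = 1000))
  zs2 <- c(geweke_z(trend$draws$sigma), geweke_z(trend$draws$rho))
  expect_equal(check_convergence(trend)$converged, all(abs(zs2) <= 2))
  bad <- mkfit(sigma = seq(0, 1, length.out = 1000) + rnorm(1000, 0, 0.05),
               tau = rep(3L, 1000), loglik = rnorm(1000))
  expect_false(check_convergence(bad)$converged)
  # all-degenerate chains are treated as converged
  const <- mkfit(sigma = rep(1, 1000), tau = rep(0L, 1000),
                 loglik = rep(0, 1000))
  expect_true(check_convergence(const)$converged)
})

test_that("summarize_run turns categories into percentages over all cells", {
  all1 <- summarize_run(rep("Level 1", 50))
  expect_equal(all1$pct[all1$category == "Level 1"], 100)
  expect_equal(sum(all1$pct), 100)

  mixed <- summarize_run(c(rep("Level 1", 7), rep("Level 2", 12),
                           rep("Level 3", 2), rep("Not successful", 28),
                           rep("No change detected", 1)))
  expect_equal(mixed$pct,
               c(14, 24, 4, 56, 2, 0)[match(mixed$category,
                 c("Level 1", "Level 2", "Level 3", "Not successful",
                   "No change detected", "Did not converge"))])
  expect_equal(sum(mixed$pct), 100)
  expect_equal(mixed$pct[mixed$category == "Did not converge"], 0)
  expect_error(summarize_run(character(0)))
  expect_error(summarize_run("Level 9"))
})
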