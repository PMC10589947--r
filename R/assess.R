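#' Detection rule: posterior mode of the change point
#'
#' A posterior mode of zero means the spike ("no change") dominates and the
#' model failed to detect a behavioral change. Ties involving zero resolve
#' conservatively to zero; ties among slab values resolve to the smallest.
#'
#' @param tau_draws Integer vector of posterior draws of `tau` (0 = spike).
#' @return A one-row tibble with `detected` (logical) and `mode` (integer).
#' @export
detect_change <- function(tau_draws) {
  if (length(tau_draws) == 0) abort("no posterior draws of tau.")
  tb <- table(tau_draws)
  top <- as.integer(names(tb)[tb == max(tb)])
  mode <- if (0L %in% top) 0L else min(top)
  tibble(detected = mode != 0L, mode = mode)
}

#' Classify the a-priori success level of a change-point estimate
#'
#' The posterior draws of `tau` are centered on the true change point and
#' converted to hours; success levels are then: **Level 1** if the 2.5%
#' and 97.5% equal-tailed quantiles both fall within the window (default
#' +/- 6 h) of the true event, else **Level 2** if the 25%/75% quantiles
#' do, else **Level 3** if the posterior median does, else
#' **unsuccessful**. When no change is detected the level is `"none"`.
#' Quantiles are computed on the slab draws only (`tau > 0`), which is the
#' only way the interval lives on the change-time scale; set
#' `include_spike = TRUE` to keep spike draws (coded at `tau = 0`).
#'
#' @param tau_draws Integer posterior draws of `tau`.
#' @param tau_true True change-point index.
#' @param fix_minutes Fix interval of the fitted data, minutes.
#' @param window_hours Half-width of the success window (default 6 h).
#' @param include_spike Include spike draws in the quantiles (default
#'   `FALSE`).
#' @return One-row tibble: `detected`, `mode`, `success_level` (factor:
#'   `"1"`, `"2"`, `"3"`, `"unsuccessful"`, `"none"`), centered quantiles
#'   `q2.5_h`, `q25_h`, `q50_h`, `q75_h`, `q97.5_h` and `width95_h`, all
#'   in hours.
#' @export
classify_success <- function(tau_draws, tau_true, fix_minutes,
                             window_hours = 6, include_spike = FALSE) {
  dc <- detect_change(tau_draws)
  lev <- c("1", "2", "3", "unsuccessful", "none")
  if (!dc$detected) {
    return(tibble(detected = FALSE, mode = dc$mode,
                  success_level = factor("none", lev),
                  q2.5_h = NA_real_, q25_h = NA_real_, q50_h = NA_real_,
                  q75_h = NA_real_, q97.5_h = NA_real_,
                  width95_h = NA_real_))
  }
  use <- if (include_spike) tau_draws else tau_draws[tau_draws > 0]
  if (length(use) == 0) abort("change detected but no slab draws available.")
  hrs <- (use - tau_true) * fix_minutes / 60
  q <- quantile(hrs, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
  win <- c(-window_hours, window_hours)
  inside <- function(lo, hi) lo >= win[1] && hi <= win[2]
  level <- if (inside(q[1], q[5])) "1"
  else if (inside(q[2], q[4])) "2"
  else if (inside(q[3], q[3])) "3"
  else "unsuccessful"
  tibble(detected = TRUE, mode = dc$mode, success_level = factor(level, lev),
         q2.5_h = q[1], q25_h = q[2], q50_h = q[3], q75_h = q[4],
         q97.5_h = q[5], width95_h = q[5] - q[1])
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of the first `frac1` of a chain against the mean of
#' the last `frac2`, with variances estimated from the spectral density at
#' frequency zero (AIC-selected autoregressive estimator). The chain is
#' flagged converged when `|z| <= 2`; the threshold is strict, so
#' `|z| = 2` exactly still counts as converged. A constant chain has an
#' undefined z and is reported as `NA` (degenerate, treated as converged
#' downstream since only likelihood-invariant parameters produce it).
#'
#' @param x Numeric vector of posterior draws (at least 100).
#' @param frac1 Fraction at the start of the chain (default 0.1).
#' @param frac2 Fraction at the end (default 0.5).
#' @return The z-score (scalar; `NA` for a degenerate chain).
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  if (n < 100) abort("need at least 100 draws for the Geweke diagnostic.")
  a <- x[seq_len(floor(frac1 * n))]
  b <- x[(n - floor(frac2 * n) + 1):n]
  if (stats::var(x) == 0) return(NA_real_)
  s0 <- function(v) {
    if (stats::var(v) == 0) return(0)
    fit <- try(ar(v, aic = TRUE, order.max = min(30, length(v) - 1)),
               silent = TRUE)
    if (inherits(fit, "try-error") || length(fit$ar) == 0) return(stats::var(v))
    fit$var.pred / (1 - sum(fit$ar))^2
  }
  va <- s0(a) / length(a)
  vb <- s0(b) / length(b)
  if (va + vb == 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(va + vb)
}

#' Convergence check of a fitted change-point model
#'
#' Applies [geweke_z()] to every continuous parameter chain; the fit is
#' converged when all finite z-scores satisfy `|z| <= 2`. Angular
#' parameters (`gamma*`) are first rotated to their circular mean and
#' re-wrapped: a chain concentrated near the support edge legitimately
#' hops between values close to `-pi` and `+pi`, which a linear diagnostic
#' would misread as non-stationarity.
#'
#' @param fit An `lcpm_fit` or `mmcpm_fit` object.
#' @param z_threshold Per-parameter flag threshold (default 2). Because
#'   each z is roughly standard normal for a healthy chain, the strict
#'   any-parameter rule has a substantial family-wise false-alarm rate;
#'   [run_grid()] uses a family-wise-calibrated threshold when judging a
#'   convergence-triggered refit.
#' @return One-row tibble with `converged`, `max_abs_z` and `n_chains`
#'   (number of chains with a finite z).
#' @export
check_convergence <- function(fit, z_threshold = 2) {
  cols <- setdiff(names(fit$draws), c("tau", "loglik"))
  z <- vapply(cols, function(cn) {
    x <- fit$draws[[cn]]
    if (startsWith(cn, "gamma")) {
      x <- wrap_to_pi(x - atan2(mean(sin(x)), mean(cos(x))))
    }
    geweke_z(x)
  }, numeric(1))
  z <- z[is.finite(z)]
  tibble(converged = length(z) == 0 || all(abs(z) <= z_threshold),
         max_abs_z = if (length(z)) max(abs(z)) else NA_real_,
         n_chains = length(z))
}

#' Assess one fitted track against a known event
#'
#' Bundles convergence checking and success classification.
#'
#' @param fit An `lcpm_fit` or `mmcpm_fit`.
#' @param tau_true True change-point index.
#' @param fix_minutes Fix interval, minutes.
#' @param window_hours Success window half-width, hours.
#' @return One-row tibble combining [classify_success()] and
#'   [check_convergence()] output, plus a `category` column used by
#'   [summarize_run()].
#' @export
assess_fit <- function(fit, tau_true, fix_minutes, window_hours = 6) {
  conv <- check_convergence(fit)
  cls <- classify_success(fit$draws$tau, tau_true, fix_minutes, window_hours)
  cat_lab <- if (!conv$converged) "Did not converge" else
    success_category(cls$detected, cls$success_level)
  dplyr::bind_cols(cls, conv, tibble(category = cat_lab))
}

# outcome label from the detection flag and success level (convergence
# already granted)
success_category <- function(detected, success_level) {
  if (!detected) return("No change detected")
  switch(as.character(success_level),
         "1" = "Level 1", "2" = "Level 2", "3" = "Level 3",
         "unsuccessful" = "Not successful")
}

assess_categories <- c("Level 1", "Level 2", "Level 3", "Not successful",
                       "No change detected", "Did not converge")

#' Summarize assessments as category percentages
#'
#' Tabulates the outcome categories (Levels 1-3, not successful, no change
#' detected, did not converge) across replicates as percentages summing to
#' 100 before rounding.
#'
#' @param assessments A tibble of [assess_fit()] rows (column `category`),
#'   or a character vector of categories.
#' @return A tibble with `category`, `n` and `pct`; every category is
#'   present (empty ones at 0).
#' @export
summarize_run <- function(assessments) {
  cats <- if (is.character(assessments)) assessments else assessments$category
  if (length(cats) == 0) abort("no assessments to summarize.")
  if (!all(cats %in% assess_categories)) {
    abort("unknown assessment category.")
  }
  n <- table(factor(cats, levels = assess_categories))
  tibble(category = assess_categories, n = as.integer(n),
         pct = 100 * as.integer(n) / length(cats))
}
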