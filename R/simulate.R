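#' Default movement-metric parameter sets for the simulation scenarios
#'
#' Pre-change movement emulates directed, extensive movement (weak angular
#' concentration around 0, longer Weibull steps); post-change movement
#' emulates encamped, tortuous post-parturition movement (reversals:
#' angular location `pi` with strong concentration, much shorter steps).
#' These generating values are the package's own surrogates and are
#' exposed here so every scenario is explicit and overridable.
#'
#' @param scenario One of `"both"`, `"angles"`, `"steps"`, `"none"`: which
#'   metrics change at the event.
#' @return List with elements `pre` and `post`, each containing `gamma`,
#'   `kappa`, `alpha`, `beta` (Weibull, metres) and `lambda` (exponential
#'   rate matched to the same mean step).
#' @export
mm_scenario_params <- function(scenario = c("both", "angles", "steps", "none")) {
  scenario <- match.arg(scenario)
  pre <- list(gamma = 0, kappa = 0.2, alpha = 1.3, beta = 120)
  post_a <- list(gamma = pi, kappa = 0.7)
  post_s <- list(alpha = 1.3, beta = 35)
  post <- switch(scenario,
                 both = c(post_a, post_s),
                 angles = c(post_a, pre[c("alpha", "beta")]),
                 steps = c(pre[c("gamma", "kappa")], post_s),
                 none = pre)
  add_lambda <- function(p) {
    p$lambda <- 1 / (p$beta * gamma(1 + 1 / p$alpha))  # rate matching Weibull mean
    p
  }
  list(pre = add_lambda(pre), post = add_lambda(post[c("gamma", "kappa", "alpha", "beta")]))
}

sim_origin <- as.POSIXct("2020-05-01 00:00:00", tz = "UTC")

#' Simulate a track under the location-model dynamics
#'
#' Generates a two-state AR(1) attractor track: `y_1 = mu1` and
#' `y_t ~ N(rho * y_{t-1} + (1 - rho) * mu_state, sigma^2 I)`, with the
#' centroid shifting from `mu1 = (-shift/2, 0)` to `mu2 = (+shift/2, 0)`
#' at the change point (the first post-event index). With `pre_hours` and
#' `post_hours` of monitoring at a `fix_minutes` interval the track has
#' `T = (pre + post) * 60 / fix + 1` locations and the true change point
#' sits at index `pre * 60 / fix + 1`.
#'
#' @param shift Distance between the two geographic centroids (metres).
#' @param sigma Observation noise SD (metres). The default 150 m gives a
#'   stationary per-coordinate SD of about 250 m at `rho = 0.8`.
#' @param rho AR(1) autocorrelation (default 0.8).
#' @param pre_hours,post_hours Monitoring duration before/after the event.
#' @param fix_minutes Fix interval in minutes.
#' @param id Individual id for the output track.
#' @param seed Optional integer seed.
#' @return A list of class `sim_track`: `track` (tibble `id`, `time`, `x`,
#'   `y`), `tau_true` (index of the first post-event location),
#'   `event_time`, and the generating parameters.
#' @export
simulate_lcpm_track <- function(shift, sigma = 150, rho = 0.8,
                                pre_hours = 48, post_hours = 48,
                                fix_minutes = 15, id = "sim",
                                seed = NULL) {
  stopifnot(shift >= 0, sigma >= 0, pre_hours > 0, post_hours > 0,
            fix_minutes > 0)
  if (!is.null(seed)) set.seed(seed)
  T <- as.integer(round((pre_hours + post_hours) * 60 / fix_minutes)) + 1L
  tau <- as.integer(round(pre_hours * 60 / fix_minutes)) + 1L
  mu1 <- c(-shift / 2, 0)
  mu2 <- c(shift / 2, 0)
  xy <- matrix(0, T, 2)
  xy[1, ] <- mu1
  for (t in 2:T) {
    mu <- if (t < tau) mu1 else mu2
    xy[t, ] <- rho * xy[t - 1, ] + (1 - rho) * mu + rnorm(2, 0, sigma)
  }
  time <- sim_origin + (seq_len(T) - 1) * fix_minutes * 60
  structure(list(track = tibble(id = id, time = time, x = xy[, 1], y = xy[, 2]),
                 tau_true = tau, event_time = time[tau],
                 params = list(shift = shift, sigma = sigma, rho = rho,
                               fix_minutes = fix_minutes)),
            class = "sim_track")
}

#' Simulate a track under the movement-metric dynamics
#'
#' Draws step lengths and turning angles per state and reconstructs
#' positions by cumulative heading (initial heading uniform on the circle,
#' initial position at the origin), so that [compute_metrics()] on the
#' returned track recovers the drawn metrics exactly. Steps are indexed
#' `t = 2..T` and angles `t = 2..T-1`; a term is post-change when
#' `t >= tau_true`, the first post-event index.
#'
#' @param scenario Which metrics change: `"both"`, `"angles"`, `"steps"`
#'   or `"none"` (see [mm_scenario_params()]); ignored when `params` is
#'   given.
#' @param family Step-length family used for generation.
#' @param params Optional list with `pre`/`post` parameter sets in the
#'   format of [mm_scenario_params()].
#' @inheritParams simulate_lcpm_track
#' @return A list of class `sim_track`: `track`, `metrics` (the drawn
#'   metrics as a [compute_metrics()]-shaped tibble), `tau_true`,
#'   `event_time`, `params`.
#' @export
simulate_mm_track <- function(scenario = c("both", "angles", "steps", "none"),
                              family = c("weibull", "exponential"),
                              params = NULL, pre_hours = 48, post_hours = 48,
                              fix_minutes = 15, id = "sim", seed = NULL) {
  family <- match.arg(family)
  if (is.null(params)) params <- mm_scenario_params(match.arg(scenario))
  if (!is.null(seed)) set.seed(seed)
  T <- as.integer(round((pre_hours + post_hours) * 60 / fix_minutes)) + 1L
  tau <- as.integer(round(pre_hours * 60 / fix_minutes)) + 1L

  draw_steps <- function(p, n) {
    if (n <= 0) return(numeric(0))
    if (family == "weibull") rstep(n, "weibull", shape = p$alpha, scale = p$beta)
    else rstep(n, "exponential", rate = p$lambda)
  }
  draw_angles <- function(p, n) {
    if (n <= 0) return(numeric(0))
    rwrappedcauchy(n, p$gamma, p$kappa)
  }
  # steps at t = 2..T: pre for t < tau
  steps <- c(draw_steps(params$pre, tau - 2L), draw_steps(params$post, T - tau + 1L))
  # angles at t = 2..T-1
  angles <- c(draw_angles(params$pre, tau - 2L),
              draw_angles(params$post, T - 1L - tau + 1L))

  heading <- runif(1, -pi, pi)
  xy <- matrix(0, T, 2)
  xy[2, ] <- xy[1, ] + steps[1] * c(cos(heading), sin(heading))
  for (t in 2:(T - 1)) {
    heading <- heading + angles[t - 1]
    xy[t + 1, ] <- xy[t, ] + steps[t] * c(cos(heading), sin(heading))
  }
  time <- sim_origin + (seq_len(T) - 1) * fix_minutes * 60
  metrics <- tibble(id = id, t = 2:T, time = time[-1], step_m = steps,
                    angle_rad = c(angles, NA_real_))
  structure(list(track = tibble(id = id, time = time, x = xy[, 1], y = xy[, 2]),
                 metrics = metrics, tau_true = tau, event_time = time[tau],
                 params = c(params, list(family = family,
                                         fix_minutes = fix_minutes))),
            class = "sim_track")
}

#' @export
print.sim_track <- function(x, ...) {
  cat(sprintf("<sim_track> T = %d, true change point at index %d (%s)\n",
              nrow(x$track), x$tau_true, format(x$event_time)))
  invisible(x)
}

#' Build the study-design scenario grid
#'
#' Emits one row per simulation-study cell for the three design
#' experiments: post-event monitoring duration (48/24/12/6/3 h post, full
#' 15-min interval), fix interval (15/30/60 min at 48 h pre / 24 h post)
#' and magnitude of change (LCPM centroid separations 1026.0, 784.5,
#' 523.0, 261.5 m, i.e. 100/75/50/25% of the largest; MMCPM scenarios
#' both/angles/steps/none), 50 replicates per cell by default. Truncation
#' and thinning cells are derived from the *same* complete replicates at
#' run time (see [run_grid()]), not re-simulated.
#'
#' @param n_replicates Replicates per cell (default 50).
#' @return A tibble with columns `experiment`, `model`, `level`, `shift`,
#'   `mm_scenario`, `pre_hours`, `post_hours`, `fix_minutes`,
#'   `n_replicates`.
#' @export
make_scenario_grid <- function(n_replicates = 50) {
  stopifnot(n_replicates >= 1)
  base_shift <- 1026.0
  grid <- dplyr::bind_rows(
    tibble(experiment = "duration", model = "both",
           level = as.character(c(48, 24, 12, 6, 3)),
           shift = base_shift, mm_scenario = "both",
           pre_hours = 48, post_hours = c(48, 24, 12, 6, 3),
           fix_minutes = 15),
    tibble(experiment = "frequency", model = "both",
           level = as.character(c(15, 30, 60)),
           shift = base_shift, mm_scenario = "both",
           pre_hours = 48, post_hours = 24,
           fix_minutes = c(15, 30, 60)),
    tibble(experiment = "magnitude", model = "lcpm",
           level = c("100%", "75%", "50%", "25%"),
           shift = c(1026.0, 784.5, 523.0, 261.5), mm_scenario = NA_character_,
           pre_hours = 48, post_hours = 48, fix_minutes = 15),
    tibble(experiment = "magnitude", model = "mmcpm",
           level = c("both", "angles", "steps", "none"),
           shift = NA_real_, mm_scenario = c("both", "angles", "steps", "none"),
           pre_hours = 48, post_hours = 48, fix_minutes = 15)
  )
  grid$n_replicates <- as.integer(n_replicates)
  grid
}
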