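#' Tidy posterior summaries of a fitted change-point model
#'
#' One row per model parameter with posterior mean, SD and equal-tailed
#' credible intervals. The change point `tau` is summarized on the slab
#' draws (`tau > 0`); its spike probability is reported by [glance()].
#'
#' @param x An `lcpm_fit` or `mmcpm_fit` object.
#' @param conf_level Credible level for the interval columns (default
#'   0.95).
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` (posterior mean),
#'   `std.error` (posterior SD), `conf.low`, `conf.high`.
#' @export
tidy.cpt_fit <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  cols <- setdiff(names(x$draws), "loglik")
  purrr::map_dfr(cols, function(cn) {
    v <- x$draws[[cn]]
    if (cn == "tau") v <- v[v > 0]
    if (length(v) == 0) {
      return(tibble(term = cn, estimate = NA_real_, std.error = NA_real_,
                    conf.low = NA_real_, conf.high = NA_real_))
    }
    q <- quantile(v, c(a, 1 - a), names = FALSE)
    tibble(term = cn, estimate = mean(v), std.error = stats::sd(v),
           conf.low = q[1], conf.high = q[2])
  })
}

#' One-row summary of a fitted change-point model
#'
#' @param x An `lcpm_fit` or `mmcpm_fit`.
#' @param ... Unused.
#' @return A tibble with `model`, `n_obs`, `n_draws`, `p_spike`
#'   (posterior probability of "no change"), `tau_mode`, `detected`,
#'   `converged`, `max_abs_z` and the mean log-likelihood.
#' @export
glance.cpt_fit <- function(x, ...) {
  dc <- detect_change(x$draws$tau)
  conv <- check_convergence(x)
  tibble(model = x$model, n_obs = x$T, n_draws = nrow(x$draws),
         p_spike = mean(x$draws$tau == 0), tau_mode = dc$mode,
         detected = dc$detected, converged = conv$converged,
         max_abs_z = conv$max_abs_z,
         mean_loglik = mean(x$draws$loglik, na.rm = TRUE))
}

#' Plot the change-point posterior of a fitted model
#'
#' Histogram of the slab draws of `tau` (with the spike probability in the
#' subtitle), optionally centered on a known event.
#'
#' @param object An `lcpm_fit` or `mmcpm_fit`.
#' @param tau_true Optional true change-point index; when given the x axis
#'   is hours relative to the event and a +/- `window_hours` band is drawn.
#' @param fix_minutes Fix interval (minutes); required with `tau_true`.
#' @param window_hours Success window half-width (default 6).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cpt_fit <- function(object, tau_true = NULL, fix_minutes = NULL,
                             window_hours = 6, ...) {
  slab <- object$draws$tau[object$draws$tau > 0]
  p_spike <- mean(object$draws$tau == 0)
  if (!is.null(tau_true)) {
    if (is.null(fix_minutes)) abort("`fix_minutes` is required with `tau_true`.")
    df <- tibble(x = (slab - tau_true) * fix_minutes / 60)
    xl <- "estimated change point (hours relative to event)"
  } else {
    df <- tibble(x = slab)
    xl <- "estimated change point (time index)"
  }
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue", colour = NA) +
    ggplot2::labs(
      x = xl, y = "posterior draws",
      title = sprintf("%s change-point posterior", toupper(object$model)),
      subtitle = sprintf("P(no change) = %.3f", p_spike)) +
    ggplot2::theme_minimal()
  if (!is.null(tau_true)) {
    g <- g + ggplot2::geom_vline(xintercept = c(-1, 1) * window_hours,
                                 linetype = "dashed", colour = "grey40") +
      ggplot2::geom_vline(xintercept = 0, colour = "red3")
  }
  g
}

#' Plot a telemetry track
#'
#' @param track Track tibble (`id`, `time`, `x`, `y`).
#' @param colour_by_time Colour the path by time (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_track <- function(track, colour_by_time = TRUE) {
  track <- validate_track(track, allow_multi = TRUE)
  g <- ggplot2::ggplot(track, ggplot2::aes(x = .data$x, y = .data$y,
                                           group = .data$id))
  if (colour_by_time) {
    g <- g + ggplot2::geom_path(ggplot2::aes(colour = .data$time)) +
      ggplot2::scale_colour_datetime(name = "time")
  } else {
    g <- g + ggplot2::geom_path()
  }
  g + ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)") +
    ggplot2::theme_minimal()
}

#' Plot a grid-run summary as a category bar chart
#'
#' @param run A `grid_run` from [run_grid()].
#' @return A ggplot object.
#' @export
plot_grid_summary <- function(run) {
  ggplot2::ggplot(run$summary,
                  ggplot2::aes(x = .data$level, y = .data$pct,
                               fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~experiment, scales = "free_x") +
    ggplot2::labs(x = "scenario level", y = "% of replicates") +
    ggplot2::theme_minimal()
}
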