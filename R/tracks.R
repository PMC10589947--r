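#' @importFrom tibble tibble as_tibble
NULL

# Validate a track tibble (single individual unless allow_multi).
# Returns the track sorted by time with `id` coerced to character.
validate_track <- function(track, allow_multi = FALSE) {
  req <- c("id", "time", "x", "y")
  miss <- setdiff(req, names(track))
  if (length(miss) > 0) {
    abort(sprintf("track is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  track <- as_tibble(track)
  track$id <- as.character(track$id)
  if (!allow_multi && length(unique(track$id)) > 1L) {
    abort("expected a single-individual track; use dplyr::group_split() or purrr::map() over ids.")
  }
  track <- dplyr::arrange(track, .data$id, .data$time)
  dup <- duplicated(track[, c("id", "time")])
  if (any(dup)) {
    abort(sprintf("duplicate timestamps at row(s): %s",
                  paste(which(dup), collapse = ", ")))
  }
  track
}

# Fix interval in minutes; errors if the track is irregular.
track_interval <- function(track, tol = 1e-6) {
  d <- as.numeric(diff(track$time), units = "mins")
  if (length(d) == 0) abort("track has fewer than 2 locations.")
  if (diff(range(d)) > tol) {
    abort("track is not on a regular time grid; use resample_linear() first.")
  }
  d[1]
}

#' Read telemetry tracks from delimited text
#'
#' Expects columns `id`, `timestamp` (ISO-8601), `x`, `y` with planar
#' coordinates in metres (e.g. UTM easting/northing); no geodesy is
#' performed. Rows are sorted by id and time; duplicate timestamps within
#' an individual are rejected.
#'
#' @param path Path to a CSV/TSV file.
#' @param delim Field delimiter; `","` by default.
#' @param tz Time zone for timestamps; default `"UTC"`.
#' @return A tibble with columns `id` (character), `time` (POSIXct),
#'   `x`, `y` (numeric, metres), one row per fix, sorted by id and time.
#' @examples
#' # a small simulated (synthetic) example track shipped with the package
#' f <- system.file("extdata", "synthetic_track.csv", package = "movecpt")
#' tr <- read_tracks(f)
#' compute_metrics(tr)
#' @export
read_tracks <- function(path, delim = ",", tz = "UTC") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  req <- c("id", "timestamp", "x", "y")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0) {
    abort(sprintf("input file is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  out <- tibble(
    id = raw$id,
    time = as.POSIXct(raw$timestamp, tz = tz,
                      tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                     "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                     "%Y-%m-%d")),
    x = as.numeric(raw$x),
    y = as.numeric(raw$y)
  )
  if (any(is.na(out$time))) {
    abort(sprintf("unparseable timestamp at row(s): %s",
                  paste(which(is.na(out$time)), collapse = ", ")))
  }
  if (any(is.na(out$x)) || any(is.na(out$y))) {
    abort("non-numeric coordinates found in `x`/`y`.")
  }
  validate_track(out, allow_multi = TRUE)
}

#' Write tracks back to delimited text
#'
#' @param track Track tibble (see [read_tracks()]).
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(track, path, delim = ",") {
  track <- validate_track(track, allow_multi = TRUE)
  out <- tibble(
    id = track$id,
    timestamp = format(track$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    x = track$x, y = track$y
  )
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Mean-center track coordinates per individual
#'
#' Subtracts each individual's mean easting and northing so that the
#' centroid prior of the location model can be placed at the origin. The
#' subtracted means are recorded in the `center_offset` attribute (a tibble
#' with one row per id) so the operation can be inverted with
#' [uncenter_locations()].
#'
#' @param track Track tibble; may contain several individuals.
#' @return The track with centered `x`, `y` and a `center_offset` attribute.
#' @export
center_locations <- function(track) {
  track <- validate_track(track, allow_multi = TRUE)
  off <- dplyr::summarise(dplyr::group_by(track, .data$id),
                          x0 = mean(.data$x), y0 = mean(.data$y),
                          .groups = "drop")
  out <- dplyr::mutate(dplyr::group_by(track, .data$id),
                       x = .data$x - mean(.data$x),
                       y = .data$y - mean(.data$y))
  out <- dplyr::ungroup(out)
  attr(out, "center_offset") <- off
  out
}

#' Undo [center_locations()]
#'
#' @param track A track previously returned by [center_locations()] (or any
#'   track plus an explicit `offset` tibble with columns `id`, `x0`, `y0`).
#' @param offset Optional offset tibble; defaults to the `center_offset`
#'   attribute.
#' @return The track with original coordinates restored.
#' @export
uncenter_locations <- function(track, offset = attr(track, "center_offset")) {
  if (is.null(offset)) abort("no `center_offset` attribute and no `offset` given.")
  track <- validate_track(track, allow_multi = TRUE)
  out <- dplyr::left_join(track, offset, by = "id")
  out <- dplyr::mutate(out, x = .data$x + .data$x0, y = .data$y + .data$y0)
  dplyr::select(out, -"x0", -"y0")
}

#' Derive step lengths and turning angles from a track
#'
#' Step length at index `t` is the Euclidean distance between locations
#' `t - 1` and `t`; the turning angle at interior index `t` is the signed
#' change of heading (counter-clockwise positive) between the displacement
#' vectors `t-1 -> t` and `t -> t+1`, wrapped to `(-pi, pi]`. Both metrics
#' are aligned to the index of the later/pivot location, so "time at or
#' after the change point" refers to movement realized at or after the
#' change. Zero-length steps leave the heading undefined: the adjacent
#' turning angles are set to `NA` (their count is reported via a warning)
#' and are dropped from the movement-metric likelihood.
#'
#' @param track Single-individual track on a regular time grid with at
#'   least 3 locations.
#' @return A tibble with one row per index `t = 2..T`: columns `id`, `t`,
#'   `time`, `step_m` (always present) and `angle_rad` (`NA` at `t = T` and
#'   next to zero-length steps).
#' @export
compute_metrics <- function(track) {
  track <- validate_track(track)
  n <- nrow(track)
  if (n < 3) abort("need at least 3 locations to derive movement metrics.")
  track_interval(track)  # enforce regularity
  dx <- diff(track$x)
  dy <- diff(track$y)
  step <- sqrt(dx^2 + dy^2)        # step ending at t = 2..T
  head <- atan2(dy, dx)            # heading of step ending at t = 2..T
  # angle at interior point t (t = 2..T-1): heading(t -> t+1) - heading(t-1 -> t)
  ang <- wrap_to_pi(head[-1] - head[-(n - 1)])
  zero <- step == 0
  bad <- zero[-(n - 1)] | zero[-1]  # angle at t invalid if step t or t+1 is zero
  if (any(bad)) {
    warn(sprintf("%d turning angle(s) undefined due to zero-length steps; set to NA.",
                 sum(bad)))
    ang[bad] <- NA_real_
  }
  tibble(
    id = track$id[-1],
    t = 2:n,
    time = track$time[-1],
    step_m = step,
    angle_rad = c(ang, NA_real_)
  )
}

#' Thin a track to a coarser fix interval
#'
#' Keeps every k-th location starting at the first, where `new_interval`
#' must be an integer multiple of the current fix interval. Movement
#' metrics must be recomputed on the thinned coordinates (steps do not
#' simply scale because paths are curved).
#'
#' @param track Single-individual regular track.
#' @param new_interval Target fix interval in minutes.
#' @return The thinned track.
#' @export
thin_to_interval <- function(track, new_interval) {
  track <- validate_track(track)
  cur <- track_interval(track)
  k <- new_interval / cur
  if (abs(k - round(k)) > 1e-9 || k < 1) {
    abort(sprintf("new interval (%s min) must be an integer multiple of the current one (%s min).",
                  new_interval, cur))
  }
  track[seq(1, nrow(track), by = round(k)), , drop = FALSE]
}

#' Truncate a track after a post-event monitoring duration
#'
#' Retains all locations with `time <= event_time + post_duration` hours,
#' emulating shorter post-event monitoring in study-design experiments.
#'
#' @param track Single-individual track.
#' @param event_time POSIXct (or numeric on the track's time scale) time of
#'   the behavioral event; must lie within the track span.
#' @param post_duration Hours of post-event data to keep.
#' @return The truncated track.
#' @export
truncate_after <- function(track, event_time, post_duration) {
  track <- validate_track(track)
  if (event_time < min(track$time) || event_time > max(track$time)) {
    abort("`event_time` lies outside the track span.")
  }
  keep <- track$time <= event_time + post_duration * 3600
  if (!any(keep)) abort("truncation removed every location.")
  track[keep, , drop = FALSE]
}

#' Resample a track onto a regular grid by linear interpolation
#'
#' Plain chord-wise linear interpolation of easting and northing onto a
#' regular grid anchored at the first fix. This is plumbing: it is not a
#' movement model and should only be used to regularize mildly irregular
#' data. Interpolated tracks carry an `interpolated` attribute.
#'
#' @param track Single-individual track with at least 2 locations.
#' @param interval Target fix interval in minutes.
#' @return A regular track flagged with `attr(, "interpolated") = TRUE`.
#' @export
resample_linear <- function(track, interval) {
  track <- validate_track(track)
  if (nrow(track) < 2) abort("need at least 2 locations to interpolate.")
  grid <- seq(min(track$time), max(track$time), by = interval * 60)
  tt <- as.numeric(track$time)
  out <- tibble(
    id = track$id[1],
    time = grid,
    x = approx(tt, track$x, xout = as.numeric(grid))$y,
    y = approx(tt, track$y, xout = as.numeric(grid))$y
  )
  attr(out, "interpolated") <- TRUE
  out
}

#' Window a track around a known event
#'
#' Convenience helper for case-study style processing: keeps data from
#' `pre_days` before to `post_days` after the event.
#'
#' @param track Single-individual track.
#' @param event_time Event time (POSIXct).
#' @param pre_days,post_days Window bounds in days (defaults 3 and 4).
#' @return The windowed track.
#' @export
window_event <- function(track, event_time, pre_days = 3, post_days = 4) {
  track <- validate_track(track)
  keep <- track$time >= event_time - pre_days * 86400 &
    track$time <= event_time + post_days * 86400
  if (!any(keep)) abort("window removed every location.")
  track[keep, , drop = FALSE]
}
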