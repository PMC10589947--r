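test_that("read_tracks parses, sorts and validates delimited files", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,timestamp,x,y",
               "a,2020-05-01T00:00:00,1,2",
               "a,2020-05-01T00:15:00,3,4",
               "a,2020-05-01T00:30:00,5,6"), f)
  tr <- read_tracks(f)
  expect_equal(nrow(tr), 3)
  expect_s3_class(tr$time, "POSIXct")
  expect_equal(tr$x, c(1, 3, 5))

  # shuffled rows give the identical track
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,timestamp,x,y",
               "a,2020-05-01T00:30:00,5,6",
               "a,2020-05-01T00:00:00,1,2",
               "a,2020-05-01T00:15:00,3,4"), f2)
  expect_equal(read_tracks(f2), tr)

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,timestamp,x", "a,2020-05-01T00:00:00,1"), f3)
  expect_error(read_tracks(f3), "y")

  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,timestamp,x,y",
               "a,2020-05-01T00:00:00,1,2",
               "a,2020-05-01T00:00:00,3,4"), f4)
  expect_error(read_tracks(f4), "duplicate")

  # round trip through write_tracks
  f5 <- withr::local_tempfile(fileext = ".csv")
  write_tracks(tr, f5)
  expect_equal(read_tracks(f5), tr)
})

test_that("center_locations zeroes the per-individual means and inverts", {
  tr <- tibble::tibble(id = "a",
                       time = as.POSIXct("2020-05-01", tz = "UTC") + 0:1 * 900,
                       x = c(5, 15), y = c(5, 5))
  ce <- center_locations(tr)
  expect_equal(ce$x, c(-5, 5))
  expect_equal(ce$y, c(0, 0))
  expect_equal(attr(ce, "center_offset")$x0, 10)
  expect_equal(attr(ce, "center_offset")$y0, 5)

  tr2 <- toy_track(20)
  ce2 <- center_locations(tr2)
  expect_lt(abs(mean(ce2$x)), 1e-9)
  expect_lt(abs(mean(ce2$y)), 1e-9)
  back <- uncenter_locations(ce2)
  expect_equal(back$x, tr2$x)
  expect_equal(back$y, tr2$y)

  # already centered: offset is zero
  ce3 <- center_locations(ce2)
  expect_equal(attr(ce3, "center_offset")$x0, 0)

  # per-individual centering with several ids
  multi <- dplyr::bind_rows(tr, dplyr::mutate(tr, id = "b", x = x + 100))
  cem <- center_locations(multi)
  ms <- dplyr::summarise(dplyr::group_by(cem, id), m = mean(x))
  expect_true(all(abs(ms$m) < 1e-9))
})

test_that("compute_metrics derives steps and CCW turning angles", {
  mk <- function(x, y) tibble::tibble(
    id = "a", time = as.POSIXct("2020-05-01", tz = "UTC") +
      (seq_along(x) - 1) * 900, x = x, y = y)

  col <- compute_metrics(mk(0:4, rep(0, 5)))  # collinear
  expect_equal(col$step_m, rep(1, 4))
  expect_equal(col$angle_rad[1:3], rep(0, 3))
  expect_true(is.na(col$angle_rad[4]))

  ra <- compute_metrics(mk(c(0, 1, 1), c(0, 0, 1)))  # right turn CCW
  expect_equal(ra$step_m, c(1, 1))
  expect_equal(ra$angle_rad[1], pi / 2)

  m10 <- compute_metrics(toy_track(10))
  expect_equal(nrow(m10), 9)                       # steps t = 2..10
  expect_equal(sum(!is.na(m10$angle_rad)), 8)      # angles t = 2..9
  expect_equal(m10$t, 2:10)

  expect_error(compute_metrics(mk(c(0, 1), c(0, 0))), "at least 3")

  # zero-length step: adjacent angles flagged missing, with a warning
  z <- mk(c(0, 1, 1, 2), c(0, 0, 0, 0))
  expect_warning(mz <- compute_metrics(z), "zero-length")
  expect_true(all(is.na(mz$angle_rad[1:2])))
})

test_that("thinning keeps every k-th fix and metrics must be recomputed", {
  sim <- simulate_lcpm_track(1026, seed = 5)
  expect_equal(nrow(sim$track), 385)
  th <- thin_to_interval(sim$track, 30)
  expect_equal(nrow(th), 193)
  expect_equal(th$time, sim$track$time[seq(1, 385, by = 2)])
  expect_equal(thin_to_interval(sim$track, 15), sim$track)  # identity
  expect_error(thin_to_interval(sim$track, 40), "multiple")

  # on a curved path the thinned steps are shorter than 2x the originals
  tr <- toy_track(21, sd = 0)
  m1 <- compute_metrics(tr)
  m2 <- compute_metrics(thin_to_interval(tr, 30))
  direct <- sqrt(diff(tr$x[seq(1, 21, 2)])^2 + diff(tr$y[seq(1, 21, 2)])^2)
  expect_equal(m2$step_m, direct, tolerance = 1e-12)
  pair_sums <- m1$step_m[seq(1, 19, 2)] + m1$step_m[seq(2, 20, 2)]
  expect_true(all(m2$step_m < pair_sums))  # triangle inequality, strict on an arc
})

test_that("truncation keeps the requested post-event span", {
  sim <- simulate_lcpm_track(1026, seed = 6)   # 48 h pre + 48 h post
  tr <- truncate_after(sim$track, sim$event_time, 24)
  expect_equal(as.numeric(difftime(max(tr$time), min(tr$time), units = "hours")),
               72)
  expect_equal(nrow(tr), 289)
  expect_equal(truncate_after(sim$track, sim$event_time, 1000), sim$track)
  t0 <- truncate_after(sim$track, sim$event_time, 0)
  expect_equal(max(t0$time), sim$event_time)
  expect_error(truncate_after(sim$track, sim$event_time - 1e9, 1))
})

test_that("linear resampling interpolates onto segments", {
  tr <- tibble::tibble(id = "a",
                       time = as.POSIXct("2020-05-01", tz = "UTC") + c(0, 3600),
                       x = c(0, 10), y = c(0, 4))
  rs <- resample_linear(tr, 30)
  expect_equal(nrow(rs), 3)
  expect_equal(rs$x[2], 5)
  expect_equal(rs$y[2], 2)
  expect_true(isTRUE(attr(rs, "interpolated")))

  reg <- toy_track(8)
  rr <- resample_linear(reg, 15)
  expect_equal(rr$x, reg$x, tolerance = 1e-9)

  # convexity: every interpolated point lies on the chord between the
  # bracketing originals
  set.seed(3)
  irr <- tibble::tibble(id = "a",
                        time = as.POSIXct("2020-05-01", tz = "UTC") +
                          sort(c(0, 3600, cumsum(runif(4, 500, 1500)))),
                        x = rnorm(6, 0, 50), y = rnorm(6, 0, 50))
  rs2 <- resample_linear(irr, 7)
  tt <- as.numeric(irr$time)
  for (i in seq_len(nrow(rs2))) {
    ti <- as.numeric(rs2$time[i])
    k <- findInterval(ti, tt, rightmost.closed = TRUE)
    lam <- (ti - tt[k]) / (tt[k + 1] - tt[k])
    if (!is.finite(lam)) lam <- 0
    expect_equal(rs2$x[i], (1 - lam) * irr$x[k] + lam * irr$x[k + 1],
                 tolerance = 1e-9)
    expect_equal(rs2$y[i], (1 - lam) * irr$y[k] + lam * irr$y[k + 1],
                 tolerance = 1e-9)
  }
})

test_that("event windowing keeps the configured bounds", {
  sim <- simulate_lcpm_track(500, pre_hours = 96, post_hours = 120, seed = 9)
  wd <- window_event(sim$track, sim$event_time, pre_days = 3, post_days = 4)
  expect_gte(min(wd$time), sim$event_time - 3 * 86400)
  expect_lte(max(wd$time), sim$event_time + 4 * 86400)
})
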