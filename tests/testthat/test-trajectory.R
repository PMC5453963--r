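test_that("trip construction validates its invariants", {
  f <- data.frame(time = as.POSIXct("2012-01-01", tz = "UTC") + c(0, 60, 60),
                  lon = c(0, 0, 0), lat = c(0, 0, 0))
  expect_error(as_trip(f, "b", "t", colony = colony), "strictly increasing")
  expect_error(as_trip(f[1, ], "b", "t", colony = colony), "at least 2")
})

test_that("speeds are distance over time with the first fix inheriting", {
  # two fixes 1 km apart in 5 minutes -> 12 km/h
  tr <- trip_from_xy(c(0, 0.6, 1.2), c(0, 0.8, 1.6))  # 1 km per 5-min step
  tr <- compute_speeds(tr)
  expect_equal(tr$speed, rep(12, 3), tolerance = 1e-3)

  still <- trip_from_xy(c(0, 0, 0), c(0, 1e-9, 2e-9))
  expect_equal(max(compute_speeds(still)$speed), 0, tolerance = 1e-6)

  bad <- trip_from_xy(c(0, 1, 2), c(0, 0, 0))
  bad$time[2] <- bad$time[1]
  expect_error(as_trip(as.data.frame(bad), "b", "t", colony = colony),
               "strictly increasing")
})

test_that("resting filter removes exactly the slow fixes and keeps the mask", {
  set.seed(2)
  n <- 60
  x <- cumsum(runif(n, 0, 3))                    # speeds 0-36 km/h
  tr <- compute_speeds(trip_from_xy(x, rep(0, n)))
  mov <- filter_resting(tr, threshold = 3)
  expect_equal(nrow(mov), sum(tr$speed >= 3))
  expect_equal(sum(attr(mov, "resting_mask")), sum(tr$speed < 3))

  fast <- compute_speeds(trip_from_xy(seq(0, 10, by = 1), rep(0, 11)))
  expect_equal(nrow(filter_resting(fast)), 11)

  slow <- compute_speeds(trip_from_xy(seq(0, 0.2, by = 0.02), rep(0, 11)))
  expect_warning(out <- filter_resting(slow), "excluded")
  expect_null(out)
})

test_that("path interpolation yields equidistant points and keeps length", {
  tr <- compute_speeds(project_trip(trip_from_xy(c(0, 0.5, 1), c(0, 0, 0))))
  path <- interpolate_path(tr, step = 0.1)
  expect_equal(nrow(path), 11)
  gaps <- sqrt(diff(path$x)^2 + diff(path$y)^2)
  expect_lt(max(abs(gaps - 0.1)), 1e-6)

  set.seed(4)
  zig <- compute_speeds(project_trip(
    trip_from_xy(cumsum(runif(40, 0.5, 2)), cumsum(rnorm(40, 0, 0.5)))))
  pz <- interpolate_path(zig, step = 0.1)
  len_orig <- sum(sqrt(diff(zig$x)^2 + diff(zig$y)^2))
  len_interp <- sum(sqrt(diff(pz$x)^2 + diff(pz$y)^2))
  expect_lt(abs(len_orig - len_interp), 0.1)
  expect_error(interpolate_path(zig, step = 0), "positive")
})

test_that("trip metrics implement the duration classes and time budgets", {
  mk <- function(days) {
    n <- days * 24 * 12 + 1
    tr <- trip_from_xy(seq(0, 10, length.out = n), rep(0, n))
    tr <- compute_speeds(tr)
    tr$ars <- rep(c(TRUE, FALSE), length.out = n)   # half the intervals
    tr
  }
  m3 <- trip_metrics(mk(3))
  m6 <- trip_metrics(mk(6))
  expect_equal(m3$class, "ST")
  expect_equal(m6$class, "LT")
  expect_equal(m3$duration_days, 3, tolerance = 1e-6)
  expect_equal(m3$pct_time_in_ars, 50, tolerance = 0.5)

  no_labels <- compute_speeds(trip_from_xy(c(0, 1, 2), c(0, 0, 0)))
  expect_warning(m <- trip_metrics(no_labels), "NA")
  expect_true(is.na(m$pct_time_in_ars))
})

test_that("metrics are invariant to duplicated colony fixes at the ends", {
  set.seed(5)
  x <- c(0, cumsum(runif(30, 0.5, 2)))
  x <- c(x, rev(x)[-1])
  tr <- compute_speeds(trip_from_xy(x, rep(0, length(x))))
  tr$ars <- tr$speed > 6
  base <- trip_metrics(tr)
  # prepend/append zero-displacement colony fixes (1 s apart -> resting)
  df <- as.data.frame(tr)[, c("time", "lon", "lat")]
  df2 <- rbind(df[1, ], df, df[nrow(df), ])
  df2$time[1] <- df$time[1] - 1
  df2$time[nrow(df2)] <- df$time[nrow(df)] + 1
  tr2 <- compute_speeds(as_trip(df2, "b1", "t1", "female", 2012L, colony))
  tr2$ars <- c(FALSE, tr$ars, FALSE)
  dup <- trip_metrics(tr2)
  expect_equal(dup$max_colony_distance_km, base$max_colony_distance_km)
  expect_lt(abs(dup$duration_days - base$duration_days), 1e-4)
  expect_equal(dup$time_flying_per_day_h, base$time_flying_per_day_h,
               tolerance = 0.05)
})

test_that("long tables round-trip through write_trips and read_trips", {
  st <- berlenga_strata()
  cfg <- generator_config()
  trips <- list(simulate_trip(st[5, ], cfg, 11, bird_id = "bA", trip_id = "t1"),
                simulate_trip(st[6, ], cfg, 12, bird_id = "bB", trip_id = "t1"))
  f <- tempfile(fileext = ".csv")
  write_trips(trips, f)
  back <- read_trips(f, colony = colony)
  expect_length(back, 2)
  expect_equal(nrow(back[[1]]), nrow(trips[[1]]))
  expect_equal(back[[2]]$lon, trips[[2]]$lon, tolerance = 1e-6)
  unlink(f)
})

test_that("radius segmentation splits a multi-trip track at the colony", {
  # one bird, two excursions separated by a colony visit
  leg <- function(t0, offset) {
    x <- c(seq(0, 20, by = 2), seq(18, 0, by = -2))
    data.frame(time = t0 + seq_along(x) * 300, lon = NA, lat = NA,
               x = x, y = offset * seq_along(x) / seq_along(x))
  }
  a <- leg(as.POSIXct("2012-08-01", tz = "UTC"), 0)
  b <- leg(as.POSIXct("2012-08-03", tz = "UTC"), 0)
  xy <- rbind(a, b)
  ll <- laea_inverse(xy$x, xy$y, colony)
  df <- data.frame(bird_id = "b1", time = format(xy$time, "%Y-%m-%dT%H:%M:%S"),
                   lon = ll$lon, lat = ll$lat)
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  trips <- read_trips(f, colony = colony,
                      cols = list(bird = "bird_id", time = "time",
                                  lon = "lon", lat = "lat"))
  expect_length(trips, 2)
  for (tr in trips) {
    d <- geo_dist_km(tr$lon, tr$lat, colony[1], colony[2])
    expect_lt(d[1], 2.1)
    expect_lt(d[length(d)], 2.1)
    expect_gt(max(d), 15)
  }
  unlink(f)
})
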