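#' Construct a foraging-trip object
#'
#' A trip is an ordered sequence of GPS fixes for one foraging excursion of
#' one bird, carrying the bird/trip identifiers, the group (sex) and year
#' labels, and the colony position. Stored as a data.frame of fixes with
#' attributes; downstream stages add columns (`x`, `y`, `speed`, `resting`,
#' `ars`) as they run.
#'
#' @param fixes data.frame with columns `time` (POSIXct, UTC), `lon`, `lat`.
#' @param bird_id,trip_id identifiers (coerced to character).
#' @param group group label, e.g. `"female"` or `"male"`.
#' @param year integer year label.
#' @param colony numeric `c(lon, lat)` of the colony.
#' @return an object of class `fs_trip`.
#' @export
as_trip <- function(fixes, bird_id, trip_id, group = NA_character_,
                    year = NA_integer_, colony) {
  stopifnot(is.data.frame(fixes), all(c("time", "lon", "lat") %in% names(fixes)))
  if (nrow(fixes) < 2) stop("a trip needs at least 2 fixes")
  dt <- diff(as.numeric(fixes$time))
  if (any(dt <= 0))
    stop("timestamps must be strictly increasing within a trip (violated at fix ",
         which(dt <= 0)[1] + 1, ")")
  if (any(abs(fixes$lat) > 90) || any(abs(fixes$lon) > 180))
    stop("coordinates out of range")
  structure(fixes,
            class = c("fs_trip", "data.frame"),
            bird_id = as.character(bird_id), trip_id = as.character(trip_id),
            group = group, year = as.integer(year), colony = colony)
}

trip_attr <- function(trip, what) attr(trip, what, exact = TRUE)

#' @export
print.fs_trip <- function(x, ...) {
  cat(sprintf("<fs_trip> bird %s trip %s (%s, %s): %d fixes, %.2f days\n",
              attr(x, "bird_id"), attr(x, "trip_id"), attr(x, "group"),
              attr(x, "year"), nrow(x),
              diff(range(as.numeric(x$time))) / 86400))
  invisible(x)
}

# keep fs_trip attributes through row subsetting
keep_trip_attrs <- function(new, old) {
  for (a in c("bird_id", "trip_id", "group", "year", "colony"))
    attr(new, a) <- attr(old, a)
  class(new) <- c("fs_trip", "data.frame")
  new
}

#' Project a trip's fixes to colony-centred equal-area coordinates
#'
#' Adds `x`, `y` columns (km) from a Lambert azimuthal equal-area projection
#' centred on the colony (or an explicit centre).
#'
#' @param trip an `fs_trip`.
#' @param center optional `c(lon, lat)`; defaults to the trip's colony.
#' @return the trip with `x`, `y` columns.
#' @export
project_trip <- function(trip, center = NULL) {
  if (is.null(center)) center <- trip_attr(trip, "colony")
  xy <- laea_project(trip$lon, trip$lat, center)
  trip$x <- xy$x
  trip$y <- xy$y
  trip
}

#' Per-fix ground speed
#'
#' Speed of each fix is the geodesic distance from the previous fix divided
#' by the elapsed time; the first fix inherits the second's speed.
#'
#' @param trip an `fs_trip`.
#' @return the trip with a `speed` column (km/h).
#' @export
compute_speeds <- function(trip) {
  n <- nrow(trip)
  dt_h <- diff(as.numeric(trip$time)) / 3600
  if (any(dt_h == 0)) stop("zero time step at fix ", which(dt_h == 0)[1] + 1)
  d <- geo_dist_km(trip$lon[-n], trip$lat[-n], trip$lon[-1], trip$lat[-1])
  sp <- d / dt_h
  trip$speed <- c(sp[1], sp)
  trip
}

#' Remove resting/drifting fixes by a speed threshold
#'
#' Fixes slower than the threshold are treated as resting on the water (or
#' ashore) and removed before first-passage-time analysis; the resting mask
#' is kept on the returned trip (attribute `resting_mask`, aligned with the
#' original fixes, which remain available as attribute `full_fixes`) so time
#' budgets can still be computed on the full trip.
#'
#' @param trip an `fs_trip` with speeds.
#' @param threshold speed cutoff in km/h (default 3).
#' @return the moving-only trip, or `NULL` (with a warning) when every fix is
#'   resting, signalling the trip should be excluded.
#' @export
filter_resting <- function(trip, threshold = 3) {
  if (is.null(trip$speed)) trip <- compute_speeds(trip)
  resting <- trip$speed < threshold
  if (all(resting)) {
    warning("all fixes below ", threshold, " km/h for trip ",
            trip_attr(trip, "trip_id"), "; trip excluded")
    return(NULL)
  }
  out <- keep_trip_attrs(trip[!resting, , drop = FALSE], trip)
  # active-time axis: the clock gap left by a removed resting bout is
  # compressed so resting does not register as slow passage in the FPT
  # analysis downstream, but never below the time the bird would need to
  # cover the bout's net drift at its typical moving speed (otherwise the
  # drift would register as implausibly fast passage instead)
  dt <- diff(as.numeric(out$time))
  med <- stats::median(dt)
  n_out <- nrow(out)
  d_step <- geo_dist_km(out$lon[-n_out], out$lat[-n_out],
                        out$lon[-1], out$lat[-1])
  v_med <- stats::median(d_step / (dt / 3600))
  dt_active <- pmin(dt, pmax(med, d_step / v_med * 3600))
  out$t_active <- cumsum(c(0, dt_active))
  attr(out, "resting_mask") <- resting
  attr(out, "full_fixes") <- as.data.frame(trip)
  out
}

#' Re-sample a path at a constant along-path distance step
#'
#' Piecewise-linear re-sampling of the projected path at `step`-km intervals
#' (default 0.1 km), with timestamps interpolated linearly within segments.
#' The end point is appended so total path length is preserved to within one
#' step.
#'
#' @param trip a projected, moving-only `fs_trip`.
#' @param step along-path interval in km.
#' @return data.frame with `s` (along-path km), `t` (numeric seconds), `x`,
#'   `y`, `lon`, `lat`.
#' @export
interpolate_path <- function(trip, step = 0.1) {
  if (step <= 0) stop("step must be positive")
  if (is.null(trip$x)) trip <- project_trip(trip)
  seg <- sqrt(diff(trip$x)^2 + diff(trip$y)^2)
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  # collapse zero-length segments so approx() sees strictly increasing s
  keep <- c(TRUE, seg > 1e-9)
  s0 <- s[keep]
  grid <- seq(0, L, by = step)
  if (L - grid[length(grid)] > 1e-9) grid <- c(grid, L)
  out <- data.frame(
    s = grid,
    t = stats::approx(s0, as.numeric(trip$time)[keep], xout = grid)$y,
    x = stats::approx(s0, trip$x[keep], xout = grid)$y,
    y = stats::approx(s0, trip$y[keep], xout = grid)$y
  )
  if (!is.null(trip$t_active))
    out$t_active <- stats::approx(s0, trip$t_active[keep], xout = grid)$y
  ll <- laea_inverse(out$x, out$y, trip_attr(trip, "colony"))
  out$lon <- ll$lon
  out$lat <- ll$lat
  attr(out, "step") <- step
  attr(out, "trip_id") <- trip_attr(trip, "trip_id")
  out
}

#' Per-trip summary metrics
#'
#' Computes the trip-level quantities used in stratum summary tables:
#' duration (days), maximum geodesic distance from the colony (km), the
#' long/short class (`LT` iff duration >= 5 days), hours spent flying per
#' day (speed >= `fly_threshold`), and the percentage of trip time spent in
#' ARS-labelled behaviour.
#'
#' @param trip an `fs_trip` with a `speed` column; an `ars` logical column
#'   (from [label_ars()]) is used for the ARS time budget.
#' @param fly_threshold speed (km/h) above which a fix counts as flying.
#' @return one-row data.frame of metrics keyed by bird/trip/group/year.
#' @export
trip_metrics <- function(trip, fly_threshold = 3) {
  if (is.null(trip$speed)) trip <- compute_speeds(trip)
  colony <- trip_attr(trip, "colony")
  tt <- as.numeric(trip$time)
  dur_days <- (tt[length(tt)] - tt[1]) / 86400
  # interval after fix i attributed to fix i; last fix carries none
  dt_h <- c(diff(tt), 0) / 3600
  dmax <- max(geo_dist_km(trip$lon, trip$lat, colony[1], colony[2]))
  fly_h <- sum(dt_h[trip$speed >= fly_threshold])
  if (is.null(trip$ars)) {
    warning("no ARS labels on trip ", trip_attr(trip, "trip_id"),
            "; pct_time_in_ars set to NA")
    pct_ars <- NA_real_
  } else {
    pct_ars <- 100 * sum(dt_h[trip$ars %in% TRUE]) / sum(dt_h)
  }
  data.frame(
    bird_id = trip_attr(trip, "bird_id"), trip_id = trip_attr(trip, "trip_id"),
    group = trip_attr(trip, "group"), year = trip_attr(trip, "year"),
    duration_days = dur_days,
    max_colony_distance_km = dmax,
    class = if (dur_days >= 5) "LT" else "ST",
    time_flying_per_day_h = fly_h / dur_days,
    pct_time_in_ars = pct_ars,
    stringsAsFactors = FALSE
  )
}

#' Read a long table of GPS fixes and split it into trips
#'
#' Reads delimited text with one fix per row and splits each bird's track
#' into foraging trips at crossings of a colony radius (default 2 km): a
#' trip starts when the track leaves the radius and ends when it re-enters.
#' Fixes inside the radius bounding a trip are kept as its first/last fix so
#' every trip starts and ends at the colony.
#'
#' @param path file path of delimited text.
#' @param colony numeric `c(lon, lat)`.
#' @param radius_km colony radius defining trip start/end.
#' @param cols named list mapping the expected fields (`bird`, `trip`,
#'   `group`, `year`, `time`, `lon`, `lat`) to column names in the file;
#'   `trip`, `group` and `year` are optional.
#' @param sep field separator (default `","`).
#' @param tz timestamp time zone (default UTC; ISO-8601 or epoch seconds).
#' @return list of `fs_trip` objects.
#' @export
read_trips <- function(path, colony, radius_km = 2,
                       cols = list(bird = "bird_id", trip = "trip_id",
                                   group = "group", year = "year",
                                   time = "time", lon = "lon", lat = "lat"),
                       sep = ",", tz = "UTC") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  tcol <- df[[cols$time]]
  df$.time <- if (is.numeric(tcol)) {
    as.POSIXct(tcol, origin = "1970-01-01", tz = tz)
  } else {
    as.POSIXct(tcol, tz = tz, format = "%Y-%m-%dT%H:%M:%S")
  }
  df$.lon <- df[[cols$lon]]
  df$.lat <- df[[cols$lat]]
  df$.bird <- as.character(df[[cols$bird]])
  has_trip <- !is.null(cols$trip) && cols$trip %in% names(df)
  trips <- list()
  for (b in unique(df$.bird)) {
    sub <- df[df$.bird == b, , drop = FALSE]
    sub <- sub[order(sub$.time), , drop = FALSE]
    if (has_trip) {
      ids <- as.character(sub[[cols$trip]])
    } else {
      ids <- segment_by_radius(sub$.lon, sub$.lat, colony, radius_km)
    }
    for (id in unique(ids[!is.na(ids)])) {
      rows <- sub[which(ids == id), , drop = FALSE]
      if (nrow(rows) < 2) next
      grp <- if (!is.null(cols$group) && cols$group %in% names(rows))
        rows[[cols$group]][1] else NA_character_
      yr <- if (!is.null(cols$year) && cols$year %in% names(rows))
        rows[[cols$year]][1] else NA_integer_
      trips[[length(trips) + 1]] <- as_trip(
        data.frame(time = rows$.time, lon = rows$.lon, lat = rows$.lat),
        bird_id = b, trip_id = id, group = grp, year = yr, colony = colony)
    }
  }
  trips
}

# Assign a trip id to each fix: runs outside the colony radius, padded with
# one bounding at-colony fix on each side. NA for fixes between trips.
segment_by_radius <- function(lon, lat, colony, radius_km) {
  d <- geo_dist_km(lon, lat, colony[1], colony[2])
  outside <- d > radius_km
  ids <- rep(NA_character_, length(lon))
  r <- rle(outside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- 0
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    k <- k + 1
    a <- max(1, starts[i] - 1)   # include the last at-colony fix before
    b <- min(length(lon), ends[i] + 1)  # and the first after return
    ids[a:b] <- sprintf("t%02d", k)
  }
  ids
}

#' Write per-trip fixes as delimited text
#'
#' One row per fix: bird_id, trip_id, group, year, ISO-8601 UTC timestamp,
#' lon, lat (WGS84 decimal degrees).
#'
#' @param trips list of `fs_trip` objects.
#' @param path output file path.
#' @export
write_trips <- function(trips, path) {
  rows <- lapply(trips, function(tr) {
    data.frame(
      bird_id = trip_attr(tr, "bird_id"), trip_id = trip_attr(tr, "trip_id"),
      group = trip_attr(tr, "group"), year = trip_attr(tr, "year"),
      time = format(tr$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      lon = tr$lon, lat = tr$lat, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
}
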