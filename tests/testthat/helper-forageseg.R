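# shared fixtures and independent oracles, all built in code

colony <- berlenga_colony()

# a straight constant-speed path in projected km (already "interpolated")
straight_path <- function(length_km = 20, v_kmh = 10, step = 0.1) {
  s <- seq(0, length_km, by = step)
  p <- data.frame(s = s, t = s / v_kmh * 3600, x = s, y = 0)
  attr(p, "step") <- step
  p
}

# a reproducible zigzag path (projected km) with irregular but valid times
zigzag_path <- function(n = 120, seed = 1, step = 0.1) {
  set.seed(seed)
  ang <- cumsum(rnorm(n, 0, 0.6))
  x <- cumsum(c(0, step * cos(ang[-1])))
  y <- cumsum(c(0, step * sin(ang[-1])))
  sp <- runif(n - 1, 4, 14)                       # km/h per segment
  tt <- cumsum(c(0, step / sp * 3600))
  p <- data.frame(s = seq(0, by = step, length.out = n), t = tt, x = x, y = y)
  attr(p, "step") <- step
  p
}

# exhaustive double-loop FPT oracle: scan outward point by point in both
# directions, interpolating the crossing time of the first point beyond r
fpt_oracle <- function(path, r) {
  x <- path$x; y <- path$y; tt <- if (!is.null(path$t_active)) path$t_active else path$t
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cross <- function(idxs) {
      d_prev <- 0; t_prev <- tt[i]
      for (j in idxs) {
        d <- sqrt((x[j] - x[i])^2 + (y[j] - y[i])^2)
        if (d > r) {
          f <- (r - d_prev) / (d - d_prev)
          return(t_prev + f * (tt[j] - t_prev))
        }
        d_prev <- d; t_prev <- tt[j]   # bracketing fix for interpolation
      }
      NA_real_
    }
    fw <- if (i < n) cross((i + 1):n) else NA_real_
    bw <- if (i > 1) cross((i - 1):1) else NA_real_
    out[i] <- (fw - bw) / 3600
  }
  out
}

# simple fs_trip at 5-min fixes from planar km offsets around the colony
trip_from_xy <- function(x, y, dt_min = 5, group = "female", year = 2012L,
                         bird = "b1", trip = "t1") {
  ll <- laea_inverse(x, y, colony)
  as_trip(data.frame(
    time = as.POSIXct("2012-08-20 06:00:00", tz = "UTC") +
      (seq_along(x) - 1) * dt_min * 60,
    lon = ll$lon, lat = ll$lat),
    bird_id = bird, trip_id = trip, group = group, year = year,
    colony = colony)
}

# uniform fs_ud over an explicit cell mask (for analytic UDOI anchors)
uniform_ud <- function(grid, mask) {
  area <- forageseg:::grid_cell_area(grid)
  dens <- matrix(0, length(grid$lat), length(grid$lon))
  dens[mask] <- 1
  dens <- dens / sum(dens * area)
  structure(list(grid = grid, dens = dens, area = area, h = NA),
            class = "fs_ud")
}
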