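#' Berlenga colony position
#'
#' The breeding colony on Berlenga Island off the Portuguese coast
#' (39 deg 23 min N, 9 deg 36 min W), the central place of all simulated
#' trips.
#'
#' @return numeric `c(lon, lat)` in decimal degrees.
#' @export
berlenga_colony <- function() c(lon = -9.6, lat = 39.3833)

#' Default per-stratum generator parameters
#'
#' One row per sex x year stratum of the six-season Cory's shearwater study
#' the generator emulates: sample sizes, trip-duration and maximum-range
#' distributions, long-trip:short-trip ratio, percentage of time in
#' area-restricted search, plasma isotope means and Bayesian standard
#' ellipse areas, body-condition-index offsets and mass gain per day at
#' sea. Years 2010, 2011 and 2013 are the poor-regime (low productivity,
#' negative winter NAO) seasons; 2012, 2014 and 2015 the good-regime ones.
#'
#' @return data.frame with one row per group x year.
#' @export
berlenga_strata <- function() {
  g <- rep(c("female", "male"), 6)
  yr <- rep(c(2010, 2011, 2012, 2013, 2014, 2015), each = 2)
  df <- data.frame(
    group = g, year = yr,
    regime = rep(c("poor", "poor", "good", "poor", "good", "good"), each = 2),
    nao_winter = rep(c(-4.6, -1.6, 3.2, -2.0, 3.1, 3.6), each = 2),
    n_trips = c(69, 50, 19, 21, 34, 40, 22, 20, 15, 16, 30, 63),
    n_birds = c(10, 9, 5, 6, 4, 5, 5, 4, 3, 4, 7, 11),
    dur_mean = c(3.9, 3.0, 3.2, 2.5, 1.5, 1.3, 2.8, 2.0, 1.4, 1.1, 1.5, 1.3),
    dur_sd   = c(1.3, 1.0, 1.1, 1.0, 0.5, 0.5, 0.9, 1.2, 0.6, 0.5, 0.7, 0.6),
    ltst_ratio = c(0.8, 0.5, 0.7, 0.4, 0.3, 0.2, 0.9, 0.5, 0.3, 0.4, 0.4, 0.2),
    dist_mean = c(823.2, 587.5, 624.2, 342.6, 194.4, 179.1,
                  542.9, 209.1, 98.1, 134.3, 58.4, 74.4),
    dist_sd = c(43.1, 54.4, 67.1, 67.1, 32.1, 44.0,
                87.3, 66.9, 22.1, 22.2, 21.0, 21.9),
    ars_mean = c(45.2, 29.9, 37.5, 29.3, 18.9, 17.3,
                 38.3, 28.7, 18.0, 18.5, 16.3, 14.2),
    ars_sd = c(6.7, 5.5, 6.2, 5.0, 3.8, 3.7, 5.8, 5.6, 2.2, 4.4, 4.9, 3.5),
    d13c_mean = c(-20.5, -18.9, -19.1, -18.0, -18.4, -17.9,
                  -19.3, -18.3, -17.4, -17.5, -17.2, -17.5),
    d13c_sd = c(0.5, 0.7, 0.6, 0.4, 0.6, 0.5, 0.4, 0.5, 0.2, 0.3, 0.6, 0.3),
    d15n_mean = c(13.9, 14.4, 13.1, 14.0, 12.8, 13.0,
                  13.4, 14.1, 12.7, 13.5, 13.2, 13.9),
    d15n_sd = c(0.4, 0.5, 0.4, 0.3, 0.3, 0.4, 0.3, 0.5, 0.4, 0.5, 0.3, 0.3),
    sea_b = c(1.8, 1.1, 1.3, 0.8, 0.8, 0.5, 1.2, 0.7, 0.7, 0.6, 0.9, 0.5),
    bci_mean = c(-1.2, -0.5, -0.9, -0.5, 0.4, 0.7,
                 -0.8, -0.4, 1.0, 1.2, 1.2, 1.4),
    bci_sd = c(0.4, 0.2, 0.5, 0.2, 0.5, 0.2, 0.2, 0.3, 0.2, 0.3, 0.3, 0.4),
    gain_mean = c(24.3, 29.0, 28.8, 31.0, 80.5, 81.6,
                  34.3, 40.9, 84.3, 86.9, 88.1, 90.0),
    gain_sd = c(8.3, 7.7, 9.3, 6.3, 9.9, 7.2, 8.3, 7.7, 6.3, 5.7, 5.6, 4.7),
    stringsAsFactors = FALSE
  )
  df
}

#' Generator configuration
#'
#' Movement and sampling parameters shared by all strata. Defaults: 5-minute
#' fix interval (the logger setting), 3 ARS patches of 5-km radius per trip,
#' 35 km/h nominal commuting ground speed, 8 km/h within-patch speed,
#' wrapped-Cauchy heading concentration 0.9 while commuting and 0.3 inside
#' patches (strong persistence vs tortuous, centre-attracted search).
#'
#' @param colony `c(lon, lat)`.
#' @param fix_interval_min GPS fix interval (minutes).
#' @param seed base seed from which per-trip seeds are split.
#' @param n_patches ARS patches per trip.
#' @param patch_radius_km patch radius (km).
#' @param commute_speed,patch_speed,rest_speed ground speeds (km/h).
#' @param commute_rho,ars_rho wrapped-Cauchy concentration of turning
#'   angles.
#' @param rest_frac_min minimum fraction of trip time resting on the water.
#' @return list of class `fs_genconfig`.
#' @export
generator_config <- function(colony = berlenga_colony(),
                             fix_interval_min = 5, seed = 42,
                             n_patches = 3, patch_radius_km = 5,
                             commute_speed = 35, patch_speed = 8,
                             rest_speed = 0.8, commute_rho = 0.9,
                             ars_rho = 0.3, rest_frac_min = 0.05) {
  stopifnot(fix_interval_min > 0, commute_speed > 0, patch_speed > 0,
            patch_radius_km > 0, n_patches >= 0)
  structure(list(colony = colony, fix_interval_min = fix_interval_min,
                 seed = seed, n_patches = n_patches,
                 patch_radius_km = patch_radius_km,
                 commute_speed = commute_speed, patch_speed = patch_speed,
                 rest_speed = rest_speed, commute_rho = commute_rho,
                 ars_rho = ars_rho, rest_frac_min = rest_frac_min),
            class = "fs_genconfig")
}

# wrapped-Cauchy turning angles, median 0, concentration rho in [0, 1)
rwrapped_cauchy <- function(n, rho) {
  if (rho >= 1) return(rep(0, n))
  2 * atan(((1 - rho) / (1 + rho)) * tan(pi * (stats::runif(n) - 0.5)))
}

# centre-attracted search heading: a wrapped-Cauchy correlated walk whose
# heading is pulled toward the patch centre with weight (d / radius)^2, so
# search effort concentrates where prey density peaks and the walk stays
# tethered to the patch
attract_heading <- function(heading, pos, centre, radius, rho) {
  d <- sqrt(sum((pos - centre)^2))
  w <- min((d / radius)^2, 1)
  h_rw <- heading + rwrapped_cauchy(1, rho)
  gap <- centre - pos
  h_ctr <- atan2(gap[2], gap[1])
  atan2((1 - w) * sin(h_rw) + w * sin(h_ctr),
        (1 - w) * cos(h_rw) + w * cos(h_ctr))
}

# truncated-normal draws by inverse CDF
rtrunc_norm <- function(n, mean, sd, a = -Inf, b = Inf) {
  pa <- stats::pnorm(a, mean, sd)
  pb <- stats::pnorm(b, mean, sd)
  if (pb - pa < 1e-12) return(rep(min(max(mean, a), b), n))
  stats::qnorm(stats::runif(n, pa, pb), mean, sd)
}

# truncated-normal mean, with a Mills-ratio fallback in extreme tails
etrunc_norm <- function(mean, sd, a = -Inf, b = Inf) {
  za <- (a - mean) / sd
  zb <- (b - mean) / sd
  p <- stats::pnorm(zb) - stats::pnorm(za)
  if (p < 1e-12) {
    if (is.finite(a) && za > 0) return(a + sd / za)   # right tail
    if (is.finite(b) && zb < 0) return(b + sd / zb)   # left tail
    return(mean)
  }
  mean + sd * (stats::dnorm(za) - stats::dnorm(zb)) / p
}

# Location shift delta such that the short/long duration mixture with
# long-trip weight w reproduces the stratum mean. Short trips live on
# [0.2, 5) days, long trips on [5, Inf). When no shift can reach the target
# (printed ratio and mean mutually inconsistent), delta = 0 is kept and the
# weight is reduced instead, prioritising the duration mean.
duration_mixture <- function(dur_mean, dur_sd, ltst_ratio) {
  w <- ltst_ratio / (1 + ltst_ratio)
  mix_mean <- function(delta, wt = w)
    wt * etrunc_norm(dur_mean + delta, dur_sd, 5, Inf) +
    (1 - wt) * etrunc_norm(dur_mean + delta, dur_sd, 0.2, 5)
  lo <- -(dur_mean - 0.2) - 4 * dur_sd
  hi <- 4 * dur_sd + 5
  if (mix_mean(lo) <= dur_mean && mix_mean(hi) >= dur_mean) {
    delta <- stats::uniroot(function(d) mix_mean(d) - dur_mean,
                            c(lo, hi), tol = 1e-8)$root
    return(list(delta = delta, w = w))
  }
  es <- etrunc_norm(dur_mean, dur_sd, 0.2, 5)
  el <- etrunc_norm(dur_mean, dur_sd, 5, Inf)
  w_eff <- min(max((dur_mean - es) / (el - es), 0), w)
  list(delta = 0, w = w_eff)
}

#' Simulate one foraging trip as a correlated random walk
#'
#' Generates a trip that leaves the colony, commutes outbound (wrapped-
#' Cauchy heading noise around the bearing to the next waypoint), works the
#' configured number of ARS patches (slow, tortuous search flight
#' alternating with sitting on the water, confined to the patch radius),
#' and commutes home, with the remaining loafing time spent drifting on the
#' commute legs. The percent-time-in-ARS target counts total patch
#' residency (search flight plus in-patch resting). The trip duration is drawn from the
#' short/long mixture implied by the stratum's long:short trip ratio, the
#' percent time in ARS and the maximum range from the stratum
#' distributions; the realized maximum range scales with the drawn duration
#' so short trips stay physically feasible. First and last fix are at the
#' colony.
#'
#' @param params one row of [berlenga_strata()] (or a list with the same
#'   fields).
#' @param config a [generator_config()].
#' @param trip_seed integer seed for this trip.
#' @param bird_id,trip_id identifiers.
#' @param start trip start time (POSIXct).
#' @return an `fs_trip`.
#' @export
simulate_trip <- function(params, config, trip_seed,
                          bird_id = "b01", trip_id = "t01",
                          start = as.POSIXct(
                            sprintf("%d-08-15 06:00:00", params$year),
                            tz = "UTC")) {
  set.seed(trip_seed)
  mix <- duration_mixture(params$dur_mean, params$dur_sd, params$ltst_ratio)
  long <- stats::runif(1) < mix$w
  D <- if (long) {
    rtrunc_norm(1, params$dur_mean + mix$delta, params$dur_sd, 5, Inf)
  } else {
    rtrunc_norm(1, params$dur_mean + mix$delta, params$dur_sd, 0.2, 5)
  }
  pA <- if (config$n_patches == 0) 0 else
    rtrunc_norm(1, params$ars_mean, params$ars_sd, 0, 100) / 100
  dmax <- max(rtrunc_norm(1, params$dist_mean, params$dist_sd, 5, Inf) *
                D / params$dur_mean, 5)
  total_h <- D * 24
  t_ars <- pA * total_h      # patch residency, in-patch resting included
  dt <- config$fix_interval_min / 60

  # route: patch centres along a random bearing, farthest at dmax - radius;
  # short trips get proportionally smaller patches so the geometry stays
  # coherent (a patch cannot span a large share of the whole range)
  theta0 <- stats::runif(1, 0, 2 * pi)
  k <- config$n_patches
  rp <- min(config$patch_radius_km, 0.25 * dmax)
  centres <- NULL
  if (k > 0) {
    fr <- if (k == 1) 1 else seq(0.7, 1, length.out = k)
    cd <- pmax((dmax - rp) * fr, rp / 2)
    lat_off <- c(stats::rnorm(max(k - 1, 0), 0, 0.03 * dmax), 0)
    centres <- cbind(cd * cos(theta0) - lat_off * sin(theta0),
                     cd * sin(theta0) + lat_off * cos(theta0))
  }
  turn_pt <- dmax * c(cos(theta0), sin(theta0))

  # loafing waypoints sit laterally off the commute axis, pushed toward the
  # colony until clear of every patch, so long drifting bouts cannot sit
  # inside the elevated-FPT halo of a patch
  side <- sample(c(-1, 1), 1)
  rest_wp <- function(frac, sgn) {
    base <- frac * c(cos(theta0), sin(theta0)) * dmax
    # with no patches the commute stays kink-free: rest on the axis
    lat <- if (k > 0) sgn * 0.2 * dmax * c(-sin(theta0), cos(theta0)) else
      c(0, 0)
    wp <- base + lat
    if (!is.null(centres)) {
      for (try in 1:20) {
        clear <- min(sqrt(rowSums(sweep(centres, 2, wp)^2))) > rp + 3
        if (clear || sqrt(sum(wp^2)) < 3) break
        wp <- wp * 0.85
      }
    }
    wp
  }
  w_rest1 <- rest_wp(0.35, side)
  w_rest2 <- rest_wp(0.45, -side)

  waypoints <- rbind(w_rest1,
                     if (k > 0) centres,
                     turn_pt, w_rest2, c(0, 0))
  route_len <- sum(sqrt(rowSums(diff(rbind(c(0, 0), waypoints))^2)))
  t_avail <- total_h * (1 - pA - config$rest_frac_min)
  v_req <- route_len / t_avail
  if (v_req > 2 * config$commute_speed)
    stop(sprintf(
      "infeasible duration/distance draw in stratum %s-%d: need %.1f km/h",
      params$group, params$year, v_req))
  v <- max(config$commute_speed, v_req)
  t_rest <- max(total_h - route_len / v - t_ars, 0)

  plan <- list()
  add <- function(p) plan[[length(plan) + 1]] <<- p
  add(list(type = "commute", to = w_rest1))
  add(list(type = "rest", hours = t_rest / 2))
  if (k > 0) {
    for (i in seq_len(k)) {
      add(list(type = "commute", to = centres[i, ]))
      add(list(type = "ars", hours = t_ars / k, centre = centres[i, ]))
    }
  }
  add(list(type = "commute", to = turn_pt))   # reach the full range
  add(list(type = "commute", to = w_rest2))
  add(list(type = "rest", hours = t_rest / 2))
  add(list(type = "commute", to = c(0, 0)))

  pos <- c(0, 0)
  heading <- theta0
  xs <- pos[1]; ys <- pos[2]
  for (ph in plan) {
    if (ph$type == "commute") {
      step0 <- v * dt / config$commute_rho
      repeat {
        gap <- ph$to - pos
        dist <- sqrt(sum(gap^2))
        if (dist < 1e-6) break
        if (dist <= step0) {             # land exactly on the waypoint
          pos <- ph$to
          xs <- c(xs, pos[1]); ys <- c(ys, pos[2])
          break
        }
        # steering noise clamped to +-60 degrees: the heavy wrapped-Cauchy
        # tail would otherwise produce spurious back-tracking kinks no
        # goal-directed commuting bird shows
        dev <- max(min(rwrapped_cauchy(1, config$commute_rho), pi / 3),
                   -pi / 3)
        heading <- atan2(gap[2], gap[1]) + dev
        pos <- pos + step0 * c(cos(heading), sin(heading))
        xs <- c(xs, pos[1]); ys <- c(ys, pos[2])
      }
    } else if (ph$type == "ars") {
      # patch residency alternates tortuous search flight (30-min bouts)
      # with sitting on the water (45-min bouts)
      n_steps <- max(round(ph$hours / dt), 1)
      move_len <- max(round(0.5 / dt), 1)
      sit_len <- max(round(0.75 / dt), 1)
      in_bout <- 0; moving <- TRUE
      step_m <- config$patch_speed * dt
      step_s <- config$rest_speed * dt
      for (s in seq_len(n_steps)) {
        if (moving) {
          heading <- attract_heading(heading, pos, ph$centre, rp,
                                     config$ars_rho)
          pos <- pos + step_m * c(cos(heading), sin(heading))
        } else {
          ang <- stats::runif(1, 0, 2 * pi)
          pos <- pos + step_s * c(cos(ang), sin(ang))
        }
        xs <- c(xs, pos[1]); ys <- c(ys, pos[2])
        in_bout <- in_bout + 1
        if (moving && in_bout >= move_len) { moving <- FALSE; in_bout <- 0 }
        else if (!moving && in_bout >= sit_len) { moving <- TRUE; in_bout <- 0 }
      }
    } else {                              # rest: slow directed drift
      n_steps <- round(ph$hours / dt)
      if (n_steps > 0) {
        # drift carries the bird slowly along its current heading (set by
        # the surface current), so resuming flight leaves no sharp kink
        stepr <- config$rest_speed * dt
        for (s in seq_len(n_steps)) {
          drift <- heading + rwrapped_cauchy(1, 0.95)
          pos <- pos + stepr * c(cos(drift), sin(drift))
          xs <- c(xs, pos[1]); ys <- c(ys, pos[2])
        }
      }
    }
  }
  n <- length(xs)
  ll <- laea_inverse(xs, ys, config$colony)
  fixes <- data.frame(time = start + (seq_len(n) - 1) * dt * 3600,
                      lon = ll$lon, lat = ll$lat)
  tr <- as_trip(fixes, bird_id = bird_id, trip_id = trip_id,
                group = params$group, year = params$year,
                colony = config$colony)
  attr(tr, "truth") <- list(duration_days = D, max_distance_km = dmax,
                            pct_ars = 100 * pA, long_trip = long,
                            patch_centres = centres, speed = v)
  tr
}

#' Simulate all trips of one stratum
#'
#' Trips are distributed round-robin over `n_birds` birds; each trip gets a
#' seed split deterministically from the configuration seed, so any trip
#' can be regenerated in isolation.
#'
#' @param params one stratum row (see [berlenga_strata()]).
#' @param config a [generator_config()].
#' @param n_trips,n_birds override the stratum sample sizes.
#' @return list of `fs_trip` objects.
#' @export
simulate_stratum_trips <- function(params, config,
                                   n_trips = params$n_trips,
                                   n_birds = params$n_birds) {
  stopifnot(n_trips >= n_birds, n_birds >= 1)
  pref <- paste0(toupper(substr(params$group, 1, 1)), params$year)
  lapply(seq_len(n_trips), function(i) {
    b <- (i - 1) %% n_birds + 1
    simulate_trip(
      params, config,
      trip_seed = split_seed(config$seed, params$group, params$year, i),
      bird_id = sprintf("%s_b%02d", pref, b),
      trip_id = sprintf("%s_t%03d", pref, i),
      start = as.POSIXct(sprintf("%d-08-15 06:00:00", params$year),
                         tz = "UTC") + (i - 1) * 86400 * 10)
  })
}

# deterministic 32-bit seed split (base seed x stratum x index)
split_seed <- function(seed, group, year, index) {
  h <- sum(utf8ToInt(paste0(group, year))) %% 1000L
  as.integer((as.numeric(seed) * 7919 + h * 104729 + index * 131) %%
               2147483647)
}

#' Simulate a controlled single-patch trip for scale-recovery experiments
#'
#' A minimal trip with known ground truth: a straight outbound commute, one
#' centre-attracted search bout in a circular patch of known radius at the
#' far end, and a straight return. Search effort scales with patch area
#' (constant effort per unit area, i.e. uniform prey density), so small and
#' large patches are searched to the same intensity. Used to validate that
#' the variance-of-log-FPT peak recovers the patch scale.
#'
#' @param patch_radius_km patch radius (km).
#' @param seed RNG seed.
#' @param commute_km one-way commute distance.
#' @param effort_h_per_km2 patch residency per unit patch area (h/km^2).
#' @param config a [generator_config()] for speeds/turning parameters.
#' @return an `fs_trip` (no resting fixes).
#' @export
simulate_scale_trial <- function(patch_radius_km, seed, commute_km = 100,
                                 effort_h_per_km2 = 0.15,
                                 config = generator_config()) {
  set.seed(seed)
  dt <- config$fix_interval_min / 60
  v <- config$commute_speed
  hours <- effort_h_per_km2 * pi * patch_radius_km^2
  centre <- c(commute_km, 0)
  out_x <- seq(0, commute_km, by = v * dt)
  xs <- out_x; ys <- rep(0, length(out_x))
  pos <- centre
  heading <- pi / 2
  step <- config$patch_speed * dt
  for (s in seq_len(round(hours / dt))) {
    heading <- attract_heading(heading, pos, centre, patch_radius_km,
                               config$ars_rho)
    pos <- pos + step * c(cos(heading), sin(heading))
    xs <- c(xs, pos[1]); ys <- c(ys, pos[2])
  }
  gap <- sqrt(sum(pos^2))
  n_back <- ceiling(gap / (v * dt))
  back <- cbind(seq(pos[1], 0, length.out = n_back + 1),
                seq(pos[2], 0, length.out = n_back + 1))[-1, ]
  xs <- c(xs, back[, 1]); ys <- c(ys, back[, 2])
  ll <- laea_inverse(xs, ys, config$colony)
  tr <- as_trip(
    data.frame(time = as.POSIXct("2012-08-15 06:00:00", tz = "UTC") +
                 (seq_along(xs) - 1) * dt * 3600,
               lon = ll$lon, lat = ll$lat),
    bird_id = "trial", trip_id = sprintf("p%g_s%d", patch_radius_km, seed),
    group = "trial", year = 2012L, colony = config$colony)
  attr(tr, "truth") <- list(patch_radius_km = patch_radius_km,
                            patch_centre = centre, residency_h = hours)
  tr
}

#' Simulate a stratum's isotope samples
#'
#' Bivariate-normal draws with the stratum mean vector and (by default) an
#' isotropic covariance whose standard ellipse area equals the configured
#' SEA_B value.
#'
#' @param params stratum row with `d13c_mean`, `d15n_mean`, `sea_b`.
#' @param n number of birds (>= 3).
#' @param seed RNG seed.
#' @param sigma optional explicit 2x2 covariance (overrides `sea_b`).
#' @return data.frame with `bird_id`, `group`, `year`, `d13C`, `d15N`.
#' @export
simulate_isotopes <- function(params, n, seed, sigma = NULL) {
  if (n < 3) stop("need n >= 3 (SEAc undefined below 3 samples)")
  if (is.null(sigma)) sigma <- diag(2) * params$sea_b / pi
  set.seed(seed)
  X <- MASS::mvrnorm(n, mu = c(params$d13c_mean, params$d15n_mean),
                     Sigma = sigma)
  data.frame(
    bird_id = sprintf("%s%d_b%02d", toupper(substr(params$group, 1, 1)),
                      params$year, seq_len(n)),
    group = params$group, year = params$year,
    d13C = X[, 1], d15N = X[, 2], stringsAsFactors = FALSE)
}

#' Simulate a stratum's morphometrics table
#'
#' Wing, tarsus, culmen and gonys height are driven by one latent size
#' factor (plus measurement noise); capture mass is a linear function of
#' size plus the stratum body-condition offset and noise; recapture mass
#' adds the stratum mass-gain rate times a drawn trip duration.
#'
#' @param params stratum row.
#' @param n_birds number of birds (>= 3).
#' @param seed RNG seed.
#' @param mass_noise_sd extra residual mass noise (g) on top of the
#'   stratum condition offsets. Default 0: the drawn condition offset is
#'   the whole mass residual, so the downstream body-condition index
#'   reproduces the configured offset distribution.
#' @param size_noise multiplier on the per-measurement noise; 0 makes the
#'   four measurements perfectly collinear with the latent size factor.
#'   The default keeps measurement error small relative to structural
#'   variation: the configured condition offsets are sub-gram, so they are
#'   only identifiable from the mass-on-size residuals when the size score
#'   is nearly noise-free (see the methods vignette).
#' @return data.frame of measurements (mm), masses (g) and the trip
#'   duration used for the recapture mass.
#' @export
simulate_morphometrics <- function(params, n_birds, seed, mass_noise_sd = 0,
                                   size_noise = 0.2) {
  if (n_birds < 3) stop("need at least 3 birds")
  set.seed(seed)
  z <- stats::rnorm(n_birds)
  bci_off <- stats::rnorm(n_birds, params$bci_mean, params$bci_sd)
  gain <- stats::rnorm(n_birds, params$gain_mean, params$gain_sd)
  dur <- rtrunc_norm(n_birds, params$dur_mean, params$dur_sd, 0.2, Inf)
  mass_cap <- 820 + 35 * z + bci_off + stats::rnorm(n_birds, 0, mass_noise_sd)
  data.frame(
    bird_id = sprintf("%s%d_b%02d", toupper(substr(params$group, 1, 1)),
                      params$year, seq_len(n_birds)),
    group = params$group, year = params$year,
    wing = 355 + 6 * z + stats::rnorm(n_birds, 0, 1.5 * size_noise),
    tarsus = 56 + 1.2 * z + stats::rnorm(n_birds, 0, 0.4 * size_noise),
    culmen = 55 + 1.5 * z + stats::rnorm(n_birds, 0, 0.5 * size_noise),
    gonys = 16 + 0.6 * z + stats::rnorm(n_birds, 0, 0.2 * size_noise),
    mass_capture = mass_cap,
    mass_recapture = mass_cap + gain * dur,
    trip_duration_days = dur,
    stringsAsFactors = FALSE)
}

#' Simulate smooth environmental rasters
#'
#' Smooth random fields on a regular lon/lat grid: SST (deg C) with an
#' offshore trend, strictly positive CHL (mg m^-3) decaying offshore, and a
#' bathymetry ramp (water depth in m, increasing offshore). "Offshore" is
#' distance from the colony, the onshore-offshore axis of this shelf
#' system.
#'
#' @param colony `c(lon, lat)`.
#' @param lon_range,lat_range raster extent (degrees).
#' @param resolution cell size (degrees, default 0.05).
#' @param seed RNG seed.
#' @param n_days layers per variable (a daily stack).
#' @param sst_base,sst_trend SST at the colony and change per 100 km
#'   offshore.
#' @param chl_base,chl_decay CHL at the colony and log-decay per 100 km.
#' @param noise_sd amplitude of the smooth random component; 0 gives
#'   deterministic fields.
#' @return list with elements `SST`, `CHL` (lists of `n_days` rasters) and
#'   `BAT` (one raster).
#' @export
simulate_env_rasters <- function(colony, lon_range, lat_range,
                                 resolution = 0.05, seed = 42, n_days = 1,
                                 sst_base = 18, sst_trend = -0.4,
                                 chl_base = 1.5, chl_decay = 0.25,
                                 noise_sd = 0.3) {
  if (resolution <= 0) stop("resolution must be positive")
  if (colony[1] < lon_range[1] || colony[1] > lon_range[2] ||
      colony[2] < lat_range[1] || colony[2] > lat_range[2])
    stop("extent must cover the colony")
  grid <- ud_grid(lon_range, lat_range, resolution)
  dcol <- distance_to_colony(grid, colony)
  set.seed(seed)
  smooth_field <- function() {
    m <- matrix(stats::rnorm(length(grid$lat) * length(grid$lon)),
                length(grid$lat), length(grid$lon))
    gauss_smooth(m, sigma = 3)
  }
  sst <- lapply(seq_len(n_days), function(d)
    env_raster(sst_base + sst_trend * dcol$values / 100 +
                 noise_sd * smooth_field(),
               grid$lon, dcol$lat, var = "SST", time = sprintf("day%02d", d)))
  chl <- lapply(seq_len(n_days), function(d)
    env_raster(exp(log(chl_base) - chl_decay * dcol$values / 100 +
                     noise_sd * smooth_field()),
               grid$lon, dcol$lat, var = "CHL", time = sprintf("day%02d", d)))
  bat <- env_raster(pmax(20 + 3.5 * dcol$values +
                           20 * noise_sd * smooth_field(), 5),
                    grid$lon, dcol$lat, var = "BAT")
  list(SST = sst, CHL = chl, BAT = bat)
}

# separable Gaussian smoothing with edge renormalization; the output is
# rescaled to unit variance so the noise amplitude is controlled upstream
gauss_smooth <- function(m, sigma) {
  half <- ceiling(3 * sigma)
  w <- stats::dnorm(-half:half, sd = sigma)
  smooth_vec <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      j <- max(1, i - half):min(n, i + half)
      ww <- w[j - i + half + 1]
      out[i] <- sum(v[j] * ww) / sum(ww)
    }
    out
  }
  sm <- apply(m, 2, smooth_vec)
  sm <- t(apply(sm, 1, smooth_vec))
  s <- stats::sd(as.vector(sm))
  if (s > 0) sm / s else sm
}
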