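st <- berlenga_strata()
cfg <- generator_config()

test_that("the stratum table satisfies its own invariants", {
  expect_equal(nrow(st), 12)
  expect_true(all(st$n_trips >= st$n_birds))
  expect_true(all(st$dur_sd > 0 & st$dist_sd > 0 & st$sea_b > 0))
  expect_true(all(st$ars_mean > 0 & st$ars_mean < 100))
  expect_setequal(unique(st$regime[st$year %in% c(2010, 2011, 2013)]), "poor")
  expect_setequal(unique(st$regime[st$year %in% c(2012, 2014, 2015)]), "good")
})

test_that("trip generation is a pure function of its seed", {
  p <- st[st$group == "male" & st$year == 2014, ]
  a <- simulate_trip(p, cfg, trip_seed = 33)
  b <- simulate_trip(p, cfg, trip_seed = 33)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- simulate_trip(p, cfg, trip_seed = 34)
  expect_false(identical(a$lon, c2$lon))
})

test_that("every trip starts and ends at the colony", {
  for (k in c(1, 4, 7, 12)) {
    for (s in 1:2) {
      tr <- simulate_trip(st[k, ], cfg, trip_seed = 100 + s)
      d <- geo_dist_km(tr$lon, tr$lat, cfg$colony[1], cfg$colony[2])
      expect_lt(d[1], 1)
      expect_lt(d[length(d)], 1)
    }
  }
})

test_that("a zero-patch configuration is a pure commute", {
  p <- st[st$group == "female" & st$year == 2012, ]
  cfg0 <- generator_config(n_patches = 0)
  tr <- simulate_trip(p, cfg0, trip_seed = 5)
  expect_equal(attr(tr, "truth")$pct_ars, 0)
  mov <- filter_resting(compute_speeds(project_trip(tr)))
  path <- interpolate_path(mov, 0.1)
  prof <- suppressWarnings(fpt_spectrum(path, 1:30, 1))
  r_star <- detect_ars_scale(prof)
  pct <- if (is.na(r_star)) 0 else {
    full <- map_ars_to_trip(mov, path, label_ars(path, r_star)$mask)
    trip_metrics(full)$pct_time_in_ars
  }
  # a small residual is intrinsic: FPT circles spanning the turnaround see
  # both passes of an out-and-back commute, so a weak large-radius variance
  # peak can survive even without any search behaviour
  expect_lt(pct, 10)
})

test_that("infeasible distance/duration combinations fail loudly", {
  p <- st[1, ]
  p$dist_mean <- 4000; p$dist_sd <- 1
  expect_error(simulate_trip(p, cfg, trip_seed = 1), "infeasible")
})

test_that("stratum trips recover the configured duration and range", {
  p <- st[st$group == "female" & st$year == 2010, ]
  trips <- lapply(1:200, function(i) simulate_trip(p, cfg, trip_seed = i))
  dur <- vapply(trips, function(tr)
    diff(range(as.numeric(tr$time))) / 86400, numeric(1))
  dmax <- vapply(trips, function(tr)
    max(geo_dist_km(tr$lon, tr$lat, cfg$colony[1], cfg$colony[2])),
    numeric(1))
  expect_lt(abs(mean(dur) - p$dur_mean), 3 * p$dur_sd / sqrt(200) + 0.1)
  expect_lt(abs(mean(dmax) - p$dist_mean), 3 * p$dist_sd / sqrt(200) + 5)
  # long-trip share matches the mixture weight implied by the LT:ST ratio
  w <- p$ltst_ratio / (1 + p$ltst_ratio)
  expect_lt(abs(mean(dur >= 5) - w), 3 * sqrt(w * (1 - w) / 200))
  # durations respect the truncation floor
  expect_gte(min(dur), 0.19)
})

test_that("isotope draws hit the configured means and ellipse area", {
  p <- st[st$group == "female" & st$year == 2010, ]
  expect_error(simulate_isotopes(p, 2, seed = 1), "n >= 3")
  iso <- simulate_isotopes(p, 10000, seed = 3)
  expect_lt(abs(mean(iso$d13C) - p$d13c_mean), 2 * sqrt(p$sea_b / pi) / 100 + 0.02)
  expect_lt(abs(mean(iso$d15N) - p$d15n_mean), 0.02)
  # eigen-decomposition oracle for the sample standard-ellipse area
  ev <- eigen(cov(cbind(iso$d13C, iso$d15N)))$values
  expect_lt(abs(pi * sqrt(prod(ev)) - p$sea_b) / p$sea_b, 0.05)
  # isotropic case: population SEA = pi * sigma^2
  p2 <- p; p2$sea_b <- pi * 0.7^2
  iso2 <- simulate_isotopes(p2, 20000, seed = 4)
  expect_lt(abs(var(iso2$d13C) - 0.49), 0.02)
  expect_identical(simulate_isotopes(p, 10, seed = 9),
                   simulate_isotopes(p, 10, seed = 9))
})

test_that("morphometrics tables are reproducible and well-formed", {
  p <- st[2, ]
  a <- simulate_morphometrics(p, 12, seed = 8)
  expect_identical(a, simulate_morphometrics(p, 12, seed = 8))
  expect_true(all(a$wing > 0 & a$tarsus > 0 & a$culmen > 0 & a$gonys > 0))
  expect_error(simulate_morphometrics(p, 2, seed = 1), "at least 3")
})

test_that("environmental rasters are smooth, positive and reproducible", {
  env <- simulate_env_rasters(colony, colony[1] + c(-2, 2),
                              colony[2] + c(-2, 2), resolution = 0.1,
                              seed = 5, n_days = 2)
  expect_length(env$SST, 2)
  expect_true(all(env$CHL[[1]]$values > 0))
  expect_true(all(env$BAT$values > 0))
  env2 <- simulate_env_rasters(colony, colony[1] + c(-2, 2),
                               colony[2] + c(-2, 2), resolution = 0.1,
                               seed = 5, n_days = 2)
  expect_identical(env$SST[[1]]$values, env2$SST[[1]]$values)

  # zero trend and zero noise give a flat field with zero gradient
  flat <- simulate_env_rasters(colony, colony[1] + c(-1, 1),
                               colony[2] + c(-1, 1), resolution = 0.1,
                               seed = 1, sst_trend = 0, noise_sd = 0)
  expect_lt(diff(range(flat$SST[[1]]$values)), 1e-9)
  expect_true(all(gradient_pc(flat$SST[[1]])$values == 0))

  expect_error(simulate_env_rasters(colony, c(0, 1), c(0, 1)), "colony")
})
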