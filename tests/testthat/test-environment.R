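mk_raster <- function(values, var = "SST") {
  env_raster(values, lon = seq(-11, -8, length.out = ncol(values)),
             lat = seq(41, 38, length.out = nrow(values)), var = var)
}

test_that("composites average over layers and respect missing cells", {
  a <- mk_raster(matrix(1, 4, 5))
  b <- mk_raster(matrix(3, 4, 5))
  expect_equal(composite_mean(list(a))$values, a$values)
  expect_equal(composite_mean(list(a, b))$values, matrix(2, 4, 5))

  set.seed(1)
  v1 <- matrix(runif(20), 4, 5); v1[sample(20, 6)] <- NA
  v2 <- matrix(runif(20), 4, 5); v2[sample(20, 6)] <- NA
  comp <- composite_mean(list(mk_raster(v1), mk_raster(v2)))
  oracle <- matrix(NA_real_, 4, 5)
  for (i in 1:4) for (j in 1:5) {
    v <- c(v1[i, j], v2[i, j])
    if (!all(is.na(v))) oracle[i, j] <- mean(v, na.rm = TRUE)
  }
  expect_equal(comp$values, oracle)
  small <- env_raster(matrix(1, 2, 2), lon = 1:2, lat = 2:1)
  expect_error(composite_mean(list(a, small)), "same grid")
})

test_that("the proportional-change gradient matches its formula and oracle", {
  expect_true(all(gradient_pc(mk_raster(matrix(5, 6, 6)))$values == 0))
  v <- matrix(1, 3, 3); v[2, 2] <- 2      # window max 2, min 1 -> 50%
  expect_equal(max(gradient_pc(mk_raster(v))$values), 50)

  set.seed(12)
  r <- mk_raster(matrix(runif(48, 0.5, 3), 6, 8))
  g <- gradient_pc(r)
  oracle <- matrix(NA_real_, 6, 8)
  for (i in 1:6) for (j in 1:8) {
    w <- r$values[max(1, i - 1):min(6, i + 1), max(1, j - 1):min(8, j + 1)]
    oracle[i, j] <- (max(w) - min(w)) * 100 / max(w)
  }
  expect_equal(g$values, oracle)
  expect_true(all(g$values >= 0 & g$values <= 100))

  neg <- mk_raster(matrix(-1, 3, 3))
  expect_true(all(is.na(gradient_pc(neg)$values)))
})

test_that("distance-to-colony is geodesic and monotone along a meridian", {
  grid <- list(lon = seq(colony[1] - 2, colony[1] + 2, by = 0.1),
               lat = seq(colony[2] - 2, colony[2] + 2, by = 0.1))
  d <- distance_to_colony(grid, colony)
  i0 <- which.min(abs(d$lat - colony[2]))
  j0 <- which.min(abs(d$lon - colony[1]))
  expect_lt(d$values[i0, j0], 8)        # colony cell, < half cell diagonal
  north <- which.min(abs(d$lat - (colony[2] + 1)))
  oracle <- geo_dist_km(d$lon[j0], d$lat[north], colony[1], colony[2])
  expect_lt(abs(d$values[north, j0] - oracle), 0.5)
  expect_lt(abs(oracle - 111.2), 1)
  expect_true(all(diff(d$values[seq(i0, 1), j0]) >= -1e-9))
})

test_that("SST anomalies subtract the baseline cell by cell", {
  set.seed(3)
  r <- mk_raster(matrix(runif(20, 15, 20), 4, 5))
  expect_true(all(sst_anomaly(r, r)$values == 0))
  warm <- r; warm$values <- warm$values + 1
  expect_equal(sst_anomaly(warm, r)$values, matrix(1, 4, 5))
  expect_equal(sst_anomaly(warm, r)$var, "ASST")
  other <- env_raster(matrix(1, 2, 2), lon = 1:2, lat = 2:1)
  expect_error(sst_anomaly(r, other), "grids differ")
})

test_that("point extraction is nearest-cell with NA outside the grid", {
  v <- matrix(seq_len(20), 4, 5)
  r <- mk_raster(v)
  expect_equal(extract_at_points(r, r$lon[3], r$lat[2]), v[2, 3])
  expect_warning(out <- extract_at_points(r, -20, 50), "outside")
  expect_true(is.na(out))
})

test_that("buffer means use great-circle distance and the 200-km default", {
  grid <- list(lon = seq(colony[1] - 4, colony[1] + 4, by = 0.1),
               lat = seq(colony[2] - 4, colony[2] + 4, by = 0.1))
  dcol <- distance_to_colony(grid, colony)
  expect_lte(buffer_mean(dcol, colony), 200)
  const <- env_raster(matrix(7, length(dcol$lat), length(dcol$lon)),
                      dcol$lon, dcol$lat)
  expect_equal(buffer_mean(const, colony, 150), 7)
})

test_that("ESRI ASCII grids round-trip including missing cells", {
  set.seed(4)
  v <- matrix(round(runif(30, 0, 10), 3), 5, 6)
  v[2, 3] <- NA
  r <- env_raster(v, lon = seq(-10, by = 0.2, length.out = 6),
                  lat = seq(40, by = -0.2, length.out = 5), var = "CHL")
  f <- tempfile(fileext = ".asc")
  write_ascii_grid(r, f)
  back <- read_ascii_grid(f, var = "CHL")
  expect_equal(back$values, r$values, tolerance = 1e-6)
  expect_equal(back$lon, r$lon, tolerance = 1e-9)
  expect_equal(back$lat, r$lat, tolerance = 1e-9)
  unlink(f)
})
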