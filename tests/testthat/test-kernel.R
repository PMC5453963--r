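test_that("LSCV bandwidth lands near the normal-reference value", {
  set.seed(21)
  x <- rnorm(500, 0, 10); y <- rnorm(500, 0, 10)
  h <- lscv_bandwidth(x, y)
  h_ref <- 10 * 500^(-1 / 6)
  expect_gt(as.numeric(h), h_ref / 2)
  expect_lt(as.numeric(h), h_ref * 2)
  # scale equivariance and determinism
  h2 <- lscv_bandwidth(2 * x, 2 * y)
  expect_equal(as.numeric(h2), 2 * as.numeric(h), tolerance = 1e-9)
  expect_equal(as.numeric(lscv_bandwidth(x, y)), as.numeric(h))
  expect_error(lscv_bandwidth(rep(1, 20), rep(2, 20)), "degenerate")
  expect_error(lscv_bandwidth(1:5, 1:5), "at least 10")
})

test_that("the UD integrates to one and peaks where the points are", {
  grid <- ud_grid(colony[1] + c(-1.5, 1.5), colony[2] + c(-1.2, 1.2))
  set.seed(3)
  xy <- data.frame(x = rnorm(150, 0, 12), y = rnorm(150, 0, 12))
  ll <- laea_inverse(xy$x, xy$y, colony)
  ud <- kde_ud(ll$lon, ll$lat, h = 8, grid, colony)
  expect_equal(sum(ud$dens * ud$area), 1, tolerance = 1e-6)
  expect_true(all(ud$dens >= 0))

  # single point: maximum at the containing cell
  ud1 <- kde_ud(colony[1] + 0.4, colony[2] + 0.4, h = 5, grid, colony)
  peak <- which(ud1$dens == max(ud1$dens), arr.ind = TRUE)
  expect_lt(abs(ud1$grid$lon[peak[2]] - (colony[1] + 0.4)), 0.051)
  expect_lt(abs(ud1$grid$lat[peak[1]] - (colony[2] + 0.4)), 0.1)

  expect_error(kde_ud(colony[1] + 5, colony[2], 5, grid, colony),
               "does not cover")
})

test_that("two separated clusters give two local density maxima", {
  set.seed(8)
  a <- laea_inverse(rnorm(100, -40, 6), rnorm(100, 0, 6), colony)
  b <- laea_inverse(rnorm(100, 40, 6), rnorm(100, 0, 6), colony)
  grid <- ud_grid(colony[1] + c(-1.5, 1.5), colony[2] + c(-1, 1))
  ud <- kde_ud(c(a$lon, b$lon), c(a$lat, b$lat), h = 6, grid, colony)
  mid_col <- which.min(abs(ud$grid$lon - colony[1]))
  left <- ud$dens[, 1:(mid_col - 2)]
  right <- ud$dens[, (mid_col + 2):ncol(ud$dens)]
  expect_gt(max(left), ud$dens[which.min(abs(rev(ud$grid$lat) - colony[2])),
                               mid_col] * 2)
  expect_gt(max(right), max(left) * 0.3)
})

test_that("contours are nested and match the Gaussian analytic area", {
  grid <- ud_grid(colony[1] + c(-2.5, 2.5), colony[2] + c(-2, 2))
  set.seed(5)
  pts <- laea_inverse(rnorm(4000, 0, 20), rnorm(4000, 0, 20), colony)
  ud <- kde_ud(pts$lon, pts$lat, h = 4, grid, colony)
  m50 <- ud_contour(ud, 50); m95 <- ud_contour(ud, 95); m99 <- ud_contour(ud, 99)
  expect_true(all(m95[m50]))
  expect_true(all(m99[m95]))
  m100 <- ud_contour(ud, 100)
  expect_equal(as.vector(m100), as.vector(ud$dens * ud$area > 0))
  # area of the 50% mask vs the analytic 50% circle of a 2D Gaussian
  sigma_eff <- sqrt(20^2 + 4^2)
  analytic <- pi * sigma_eff^2 * (-2 * log(0.5))
  expect_lt(abs(sum(ud$area[m50]) - analytic) / analytic, 0.2)
})

test_that("UDOI anchors: identical uniforms give 1, disjoint give 0", {
  grid <- ud_grid(colony[1] + c(-1, 1), colony[2] + c(-1, 1), cell = 0.1)
  n_lat <- length(grid$lat); n_lon <- length(grid$lon)
  left <- matrix(FALSE, n_lat, n_lon); left[, 1:8] <- TRUE
  right <- matrix(FALSE, n_lat, n_lon); right[, 11:18] <- TRUE
  ud_l <- uniform_ud(grid, left)
  ud_r <- uniform_ud(grid, right)
  # at full support the index is exactly 1 for identical uniform UDs
  expect_equal(overlap_udoi(ud_l, ud_l, 100), 1, tolerance = 1e-9)
  expect_equal(overlap_udoi(ud_l, ud_r, 100), 0)
  set.seed(2)
  a <- laea_inverse(rnorm(80, -10, 15), rnorm(80, 0, 15), colony)
  b <- laea_inverse(rnorm(80, 10, 15), rnorm(80, 0, 15), colony)
  grid2 <- ud_grid(colony[1] + c(-1.5, 1.5), colony[2] + c(-1.2, 1.2))
  ua <- kde_ud(a$lon, a$lat, 8, grid2, colony)
  ub <- kde_ud(b$lon, b$lat, 8, grid2, colony)
  expect_equal(overlap_udoi(ua, ub, 95), overlap_udoi(ub, ua, 95))
  expect_error(overlap_udoi(ua, ud_l, 95), "grid")
})

test_that("UDOI on offset Gaussians matches a refined-grid oracle", {
  # UDs built from analytic Gaussian densities on the analysis grid vs a
  # 5x finer grid; full-support masks so the comparison is pure quadrature
  gauss_ud <- function(cell, mu_x) {
    grid <- ud_grid(colony[1] + c(-1.6, 1.6), colony[2] + c(-1.3, 1.3), cell)
    cc <- expand.grid(lon = grid$lon, lat = grid$lat)
    xy <- laea_project(cc$lon, cc$lat, colony)
    dens <- matrix(exp(-((xy$x - mu_x)^2 + xy$y^2) / (2 * 15^2)),
                   nrow = length(grid$lat), byrow = TRUE)
    area <- forageseg:::grid_cell_area(grid)
    structure(list(grid = grid, dens = dens / sum(dens * area), area = area,
                   h = NA), class = "fs_ud")
  }
  coarse <- overlap_udoi(gauss_ud(0.05, -12), gauss_ud(0.05, 12), 99.999)
  fine <- overlap_udoi(gauss_ud(0.01, -12), gauss_ud(0.01, 12), 99.999)
  expect_lt(abs(coarse - fine) / fine, 0.02)
})

test_that("randomization test behaves at the two degenerate extremes", {
  mk_birds <- function(cx, prefix, n_birds = 6, n = 25, sd = 6) {
    do.call(rbind, lapply(seq_len(n_birds), function(b) {
      set.seed(b + round(abs(cx)))
      ll <- laea_inverse(rnorm(n, cx, sd), rnorm(n, 0, sd), colony)
      data.frame(bird_id = paste0(prefix, b), lon = ll$lon, lat = ll$lat)
    }))
  }
  # every bird carries the same point set -> any relabelling reproduces the
  # same pair of UDs -> every permutation ties -> P = 1
  set.seed(99)
  ll <- laea_inverse(rnorm(25, 0, 6), rnorm(25, 0, 6), colony)
  same <- do.call(rbind, lapply(1:12, function(b)
    data.frame(bird_id = paste0("b", b),
               group = ifelse(b <= 6, "female", "male"),
               lon = ll$lon, lat = ll$lat)))
  res <- randomization_test(same, h = 6, center = colony,
                            n_perm = 50, seed = 1)
  expect_true(all(res$p == 1))

  # disjoint supports -> observed overlap 0, near-minimal P
  d1 <- mk_birds(-80, "fa"); d1$group <- "female"
  d2 <- mk_birds(80, "ma"); d2$group <- "male"
  res2 <- randomization_test(rbind(d1, d2), h = 6, center = colony,
                             n_perm = 99, seed = 1)
  expect_true(all(res2$observed < 1e-12))
  expect_true(all(res2$p < 0.06))

  expect_error(randomization_test(rbind(a, b), h = 6, center = colony,
                                  n_perm = 0), "n_perm")
})

test_that("the permutation P is invariant to which group is labelled first", {
  set.seed(9)
  pts <- do.call(rbind, lapply(1:8, function(b) {
    ll <- laea_inverse(rnorm(20, ifelse(b <= 4, -15, 15), 10),
                       rnorm(20, 0, 10), colony)
    data.frame(bird_id = paste0("b", b),
               group = ifelse(b <= 4, "female", "male"),
               lon = ll$lon, lat = ll$lat)
  }))
  r1 <- randomization_test(pts, h = 8, center = colony, n_perm = 60, seed = 4)
  pts2 <- pts
  pts2$group <- ifelse(pts$group == "female", "male", "female")
  r2 <- randomization_test(pts2, h = 8, center = colony, n_perm = 60, seed = 4)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$observed, r2$observed)
})
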