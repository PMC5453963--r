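#' Define a regular lon/lat analysis grid
#'
#' Cell centres on a regular grid at `cell` degrees (default 0.05, matching
#' the environmental-predictor grid).
#'
#' @param lon_range,lat_range numeric length-2 extents (degrees).
#' @param cell cell size in degrees.
#' @return list with `lon`, `lat` (cell-centre vectors) and `cell`.
#' @export
ud_grid <- function(lon_range, lat_range, cell = 0.05) {
  if (cell <= 0) stop("cell size must be positive")
  list(lon = seq(lon_range[1] + cell / 2, lon_range[2], by = cell),
       lat = seq(lat_range[1] + cell / 2, lat_range[2], by = cell),
       cell = cell)
}

# cell area matrix (km^2), rows = lat, cols = lon
grid_cell_area <- function(grid) {
  R <- 6371.0088
  dl <- grid$cell * pi / 180 * R
  matrix(dl * dl * cos(grid$lat * pi / 180),
         nrow = length(grid$lat), ncol = length(grid$lon))
}

#' Least-squares cross-validation bandwidth for a bivariate Gaussian kernel
#'
#' Minimizes the exact LSCV score of a common-bandwidth bivariate Gaussian
#' kernel density estimate over a log-spaced candidate grid. Intended to be
#' computed once on a reference point set and reused for all other group/
#' year estimates of the same study.
#'
#' @param x,y projected point coordinates (km).
#' @param n_candidates number of candidate bandwidths.
#' @param range_factor candidates span the normal-reference bandwidth
#'   divided/multiplied by this factor.
#' @param max_points point sets larger than this are subsampled (with a
#'   warning, deterministically) before scoring, as the score is O(n^2).
#' @return bandwidth h in km, with the score table as attribute `"scores"`.
#' @export
lscv_bandwidth <- function(x, y, n_candidates = 40, range_factor = 8,
                           max_points = 4000) {
  n <- length(x)
  if (n < 10) stop("need at least 10 points for LSCV")
  if (stats::sd(x) < 1e-9 && stats::sd(y) < 1e-9)
    stop("degenerate point set: all points identical")
  if (n > max_points) {
    warning("subsampling ", max_points, " of ", n, " points for LSCV")
    keep <- round(seq(1, n, length.out = max_points))
    x <- x[keep]; y <- y[keep]; n <- max_points
  }
  # bivariate normal-reference pilot: h0 = sigma * n^(-1/6)
  sig <- sqrt((stats::var(x) + stats::var(y)) / 2)
  h0 <- sig * n^(-1 / 6)
  hs <- exp(seq(log(h0 / range_factor), log(h0 * range_factor),
                length.out = n_candidates))
  d2 <- (outer(x, x, "-"))^2 + (outer(y, y, "-"))^2
  off <- d2[upper.tri(d2)]
  score <- vapply(hs, function(h) {
    # integral of fhat^2: pairwise N(0, 2h^2 I) terms (diagonal included)
    int_f2 <- (n + 2 * sum(exp(-off / (4 * h^2)))) / (n^2 * 4 * pi * h^2)
    loo <- 2 * sum(exp(-off / (2 * h^2))) / (n * (n - 1) * 2 * pi * h^2)
    int_f2 - 2 * loo
  }, numeric(1))
  h <- hs[which.min(score)]
  attr(h, "scores") <- data.frame(h = hs, lscv = score)
  h
}

#' Kernel utilization distribution on a lon/lat grid
#'
#' Gaussian-kernel density of a point set evaluated at the cell centres of a
#' regular lon/lat grid. The kernel is computed in projected (equal-area)
#' kilometres, since a Gaussian kernel is ill-defined on raw degrees at
#' mid-latitudes, and the result is renormalized so that
#' sum(density * cell area) = 1 over the grid.
#'
#' @param lon,lat point coordinates (degrees).
#' @param h bandwidth in km.
#' @param grid grid from [ud_grid()].
#' @param center projection centre `c(lon, lat)` (the colony).
#' @return an `fs_ud`: list with `grid`, `dens` (lat x lon matrix, per-km^2),
#'   `area` (cell areas, km^2), `h`.
#' @export
kde_ud <- function(lon, lat, h, grid, center) {
  if (h <= 0) stop("bandwidth must be positive")
  if (min(lon) < min(grid$lon) - grid$cell || max(lon) > max(grid$lon) + grid$cell ||
      min(lat) < min(grid$lat) - grid$cell || max(lat) > max(grid$lat) + grid$cell)
    stop(sprintf(
      "grid does not cover the point cloud; need lon [%.2f, %.2f], lat [%.2f, %.2f]",
      min(lon), max(lon), min(lat), max(lat)))
  K <- kernel_field(lon, lat, h, grid, center)
  area <- grid_cell_area(grid)
  dens <- K / sum(K * area)
  structure(list(grid = grid, dens = dens, area = area, h = h),
            class = "fs_ud")
}

# unnormalized Gaussian kernel sum over points, at grid cell centres (km)
kernel_field <- function(lon, lat, h, grid, center, chunk = 256L) {
  cc <- expand.grid(lon = grid$lon, lat = grid$lat)  # lon varies fastest
  cxy <- laea_project(cc$lon, cc$lat, center)
  pxy <- laea_project(lon, lat, center)
  acc <- numeric(nrow(cc))
  n <- length(lon)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    d2 <- outer(cxy$x, pxy$x[i:j], "-")^2 + outer(cxy$y, pxy$y[i:j], "-")^2
    acc <- acc + rowSums(exp(-d2 / (2 * h^2)))
    i <- j + 1L
  }
  # rows = lat, cols = lon
  matrix(acc, nrow = length(grid$lat), ncol = length(grid$lon), byrow = TRUE)
}

#' Probability contour mask of a utilization distribution
#'
#' The smallest set of highest-density cells whose summed probability mass
#' reaches `level` percent. Masks are nested across levels.
#'
#' @param ud an `fs_ud`.
#' @param level contour level in percent, in (0, 100].
#' @return logical matrix (lat x lon).
#' @export
ud_contour <- function(ud, level) {
  if (level <= 0 || level > 100) stop("level must be in (0, 100]")
  matrix(contour_mask(ud$dens, ud$area, level), nrow = nrow(ud$dens))
}

#' Utilization distribution overlap index (UDOI)
#'
#' Overlap between two UDs on the same grid, restricted to the union of
#' their `level`% contour masks: UDOI = (area of the union) x
#' sum(UD_a * UD_b * cell area) over that union. Symmetric; equals 1 for two
#' identical uniform distributions; exceeds 1 when two nonuniform
#' distributions overlap strongly.
#'
#' @param ud_a,ud_b `fs_ud` objects on identical grids.
#' @param level contour level in percent.
#' @return the overlap value.
#' @export
overlap_udoi <- function(ud_a, ud_b, level = 95) {
  if (!isTRUE(all.equal(ud_a$grid, ud_b$grid)))
    stop("UDs must share the same grid")
  m <- ud_contour(ud_a, level) | ud_contour(ud_b, level)
  udoi_masked(ud_a$dens, ud_b$dens, ud_a$area, m)
}

udoi_masked <- function(dens_a, dens_b, area, mask) {
  sum(area[mask]) * sum(dens_a[mask] * dens_b[mask] * area[mask])
}

#' Bird-level randomization test of between-group UD overlap
#'
#' Computes the observed UD overlap (UDOI) between two groups at each
#' contour level, then reshuffles bird-level group labels (all of a bird's
#' points move together, preserving group sizes) `n_perm` times and
#' recomputes the overlap. Under segregation the observed overlap is small
#' relative to the randomized ones, so the P-value is the (tie-included)
#' proportion of randomized overlaps at or below the observed:
#' P = (1 + #\{perm <= obs\}) / (1 + n_perm).
#'
#' @param points data.frame with columns `bird_id`, `group`, `lon`, `lat`
#'   (ARS locations of every bird, one study year).
#' @param h kernel bandwidth (km), normally the cached reference bandwidth.
#' @param grid grid from [ud_grid()]; defaults to the 0.05-degree bounding
#'   grid of the points padded by `4h`.
#' @param center projection centre (colony).
#' @param levels contour levels in percent.
#' @param n_perm number of randomizations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return data.frame with one row per level: `level`, `observed`,
#'   `randomized` (permutation mean), `n_perm`, `p`.
#' @export
randomization_test <- function(points, h, center, grid = NULL,
                               levels = c(50, 95, 99), n_perm = 1000,
                               seed = 42) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  groups <- unique(points$group)
  if (length(groups) != 2) stop("exactly two groups required")
  birds <- unique(points$bird_id)
  bird_group <- vapply(birds, function(b)
    as.character(points$group[points$bird_id == b][1]), character(1))
  if (min(table(bird_group)) < 2) stop("need at least 2 birds per group")
  if (is.null(grid)) {
    pad <- 4 * h / 100   # ~km to degrees
    grid <- ud_grid(range(points$lon) + c(-pad, pad),
                    range(points$lat) + c(-pad, pad))
  }
  area <- grid_cell_area(grid)
  # per-bird unnormalized kernel fields; a group's field is their sum
  fields <- lapply(birds, function(b) {
    rows <- points$bird_id == b
    kernel_field(points$lon[rows], points$lat[rows], h, grid, center)
  })
  names(fields) <- birds
  group_ud <- function(members) {
    K <- Reduce(`+`, fields[members])
    K / sum(K * area)
  }
  overlap_levels <- function(da, db) {
    ma <- lapply(levels, function(l) contour_mask(da, area, l))
    mb <- lapply(levels, function(l) contour_mask(db, area, l))
    vapply(seq_along(levels), function(i)
      udoi_masked(da, db, area, ma[[i]] | mb[[i]]), numeric(1))
  }
  obs <- overlap_levels(group_ud(birds[bird_group == groups[1]]),
                        group_ud(birds[bird_group == groups[2]]))
  n_a <- sum(bird_group == groups[1])
  perm <- matrix(NA_real_, n_perm, length(levels))
  set.seed(seed)
  for (p in seq_len(n_perm)) {
    shuffled <- sample(birds)
    perm[p, ] <- overlap_levels(group_ud(shuffled[seq_len(n_a)]),
                                group_ud(shuffled[-seq_len(n_a)]))
  }
  data.frame(
    level = levels,
    observed = obs,
    randomized = colMeans(perm),
    n_perm = n_perm,
    p = vapply(seq_along(levels), function(i)
      (1 + sum(perm[, i] <= obs[i] + 1e-12)) / (1 + n_perm), numeric(1))
  )
}

contour_mask <- function(dens, area, level) {
  mass <- as.vector(dens * area)
  if (level >= 100) return(matrix(mass > 0, nrow = nrow(dens)))
  ord <- order(mass, decreasing = TRUE)
  cum <- cumsum(mass[ord])
  k <- which(cum >= level / 100)[1]
  if (is.na(k)) k <- length(ord)
  mask <- logical(length(mass))
  mask[ord[seq_len(k)]] <- mass[ord[seq_len(k)]] > 0
  matrix(mask, nrow = nrow(dens))
}
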