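#' First passage time along a path
#'
#' The first passage time (FPT) at a path location is the time the animal
#' takes to cross a circle of radius `r` centred on that location: the
#' interval between the backward and forward first crossings, with crossing
#' times interpolated linearly between the bracketing path points. FPT is
#' undefined (NA) where the path never leaves the circle in one of the two
#' directions (e.g. near the ends of the track). When the path carries an
#' active-time axis (`t_active`, from [filter_resting()]), passage is
#' measured on it, so time spent resting on the water does not register as
#' slow passage.
#'
#' @param path interpolated path data.frame from [interpolate_path()]
#'   (columns `x`, `y` in km and `t` in seconds).
#' @param r circle radius in km (single positive value).
#' @param idx integer indices of the locations to evaluate (default: all).
#' @return numeric vector of FPT values in hours, NA where undefined.
#' @export
first_passage_time <- function(path, r, idx = seq_len(nrow(path))) {
  if (length(r) != 1 || r <= 0) stop("r must be a single positive radius")
  fpt_multi(path$x, path$y, path$t_active %||% path$t, idx, r)[, 1]
}

# FPT (hours) for locations `idx` at every radius in `r_vec`.
# Returns a length(idx) x length(r_vec) matrix.
fpt_multi <- function(x, y, t, idx, r_vec, chunk = 2048L) {
  nr <- length(r_vec)
  out <- matrix(NA_real_, length(idx), nr)
  rmax <- max(r_vec)
  n <- length(x)
  for (k in seq_along(idx)) {
    i <- idx[k]
    fw <- scan_crossings(x, y, t, i, r_vec, rmax, forward = TRUE, n, chunk)
    if (all(is.na(fw))) next
    bw <- scan_crossings(x, y, t, i, r_vec, rmax, forward = FALSE, n, chunk)
    out[k, ] <- (fw - bw) / 3600
  }
  out
}

# Crossing time (seconds) of each radius in r_vec scanning from location i.
# Scans outward in chunks until the running max distance exceeds rmax (or the
# path ends); first-crossing indices for all radii are then read off the
# cumulative-max sequence, which is sorted, via findInterval.
scan_crossings <- function(x, y, t, i, r_vec, rmax, forward, n, chunk) {
  seq_idx <- if (forward) {
    if (i >= n) return(rep(NA_real_, length(r_vec)))
    (i + 1L):n
  } else {
    if (i <= 1L) return(rep(NA_real_, length(r_vec)))
    (i - 1L):1L
  }
  xi <- x[i]; yi <- y[i]
  d <- numeric(0)
  taken <- 0L
  total <- length(seq_idx)
  while (taken < total) {
    take <- seq_idx[(taken + 1L):min(taken + chunk, total)]
    d <- c(d, sqrt((x[take] - xi)^2 + (y[take] - yi)^2))
    taken <- taken + length(take)
    if (max(d) > rmax) break
  }
  cm <- cummax(d)
  ks <- findInterval(r_vec, cm) + 1L   # first index where cummax exceeds r
  tcross <- rep(NA_real_, length(r_vec))
  ok <- ks <= length(d) & cm[pmin(ks, length(d))] > r_vec
  if (any(ok)) {
    kk <- ks[ok]
    t_seq <- t[seq_idx[seq_len(max(kk))]]
    d_prev <- ifelse(kk == 1L, 0, d[pmax(kk - 1L, 1L)])
    t_prev <- ifelse(kk == 1L, t[i], t_seq[pmax(kk - 1L, 1L)])
    f <- (r_vec[ok] - d_prev) / (d[kk] - d_prev)
    tcross[ok] <- t_prev + f * (t_seq[kk] - t_prev)
  }
  tcross
}

#' Named radius-grid presets for FPT analysis
#'
#' Two standard passes: `"large"` evaluates FPT every 1 km along the path
#' for radii 1 to 50 km in 1-km increments (whole-trip scale), `"small"`
#' every 0.1 km for radii 0.1 to 10 km (within-zone scale).
#'
#' @param name `"large"` or `"small"`.
#' @return list with `r_grid` (km) and `sample_step` (km).
#' @export
fpt_preset <- function(name = c("large", "small")) {
  switch(match.arg(name),
         large = list(r_grid = seq(1, 50, by = 1), sample_step = 1),
         small = list(r_grid = round(seq(0.1, 10, by = 0.1), 10),
                      sample_step = 0.1))
}

#' FPT spectrum: variance of log FPT across radii
#'
#' Evaluates FPT at path locations spaced `sample_step` km apart for every
#' radius in `r_grid`, and computes the variance of log(FPT) per radius over
#' the locations where FPT is defined. FPT is log-transformed so the
#' variance is independent of the magnitude of the mean. A peak in this
#' spectrum marks the spatial scale of area-restricted search.
#'
#' @param path interpolated path from [interpolate_path()].
#' @param r_grid radii (km); defaults to the `"large"` preset.
#' @param sample_step along-path spacing (km) of evaluation locations;
#'   defaults to the preset's spacing.
#' @param min_defined radii with fewer defined FPT values than this get an
#'   NA variance (with a warning).
#' @return an `fs_fpt_profile`: list with `r` (radius grid), `fpt`
#'   (locations x radii matrix, hours), `var_log_fpt`, `eval_idx`
#'   (row indices into `path`), and `path_step`.
#' @export
fpt_spectrum <- function(path, r_grid = NULL, sample_step = NULL,
                         min_defined = 5) {
  if (is.null(r_grid)) {
    p <- fpt_preset("large")
    r_grid <- p$r_grid
    if (is.null(sample_step)) sample_step <- p$sample_step
  }
  if (is.null(sample_step)) sample_step <- attr(path, "step")
  if (any(r_grid <= 0)) stop("radii must be positive")
  step <- attr(path, "step")
  every <- max(1L, round(sample_step / step))
  eval_idx <- seq(1L, nrow(path), by = every)
  fpt <- fpt_multi(path$x, path$y, path$t_active %||% path$t, eval_idx, r_grid)
  v <- apply(fpt, 2, function(col) {
    ok <- is.finite(col) & col > 0
    if (sum(ok) < min_defined) NA_real_ else stats::var(log(col[ok]))
  })
  if (anyNA(v))
    warning(sum(is.na(v)), " radii with fewer than ", min_defined,
            " defined FPT values; variance set NA")
  structure(list(r = r_grid, fpt = fpt, var_log_fpt = v,
                 eval_idx = eval_idx, path_step = step,
                 trip_id = attr(path, "trip_id")),
            class = "fs_fpt_profile")
}

#' Detect the ARS scale from an FPT spectrum
#'
#' The ARS scale is the radius at the global maximum of the variance of
#' log(FPT). A flat spectrum (maximum variance below `min_var`) means no
#' detectable area-restricted search and returns NA. Ties go to the smaller
#' radius.
#'
#' @param profile an `fs_fpt_profile` from [fpt_spectrum()].
#' @param min_var minimum peak variance for a scale to count (default 0.01).
#' @return the ARS scale r* in km, or NA.
#' @export
detect_ars_scale <- function(profile, min_var = 0.01) {
  v <- profile$var_log_fpt
  if (all(is.na(v))) {
    warning("all spectrum variances undefined; no ARS scale")
    return(NA_real_)
  }
  vmax <- max(v, na.rm = TRUE)
  if (vmax < min_var) return(NA_real_)
  profile$r[which.max(v)]   # first maximum = smaller radius on ties
}

#' Label ARS locations and delimit ARS zones
#'
#' A path location is in area-restricted search when its FPT at the detected
#' scale r* exceeds the trip-level mean of defined FPT(r*) values. Maximal
#' runs of at least `min_run` consecutive labelled locations form ARS zones
#' (entry/exit indices and times, centroid, scale).
#'
#' @param path interpolated path from [interpolate_path()].
#' @param r_star ARS scale in km (from [detect_ars_scale()]).
#' @param min_run minimum run length in interpolated locations (default 10,
#'   i.e. 1 km at the 0.1-km step).
#' @return list with `mask` (logical per path location) and `zones`
#'   (data.frame: zone, entry_idx, exit_idx, entry_time, exit_time,
#'   duration_h, centroid_lon, centroid_lat, scale_km).
#' @export
label_ars <- function(path, r_star, min_run = 10) {
  if (is.na(r_star)) stop("r_star is NA; no ARS scale to label at")
  fpt <- first_passage_time(path, r_star)
  ok <- is.finite(fpt)
  thr <- mean(fpt[ok])
  mask <- ok & fpt > thr * (1 + 1e-12)
  zones <- data.frame(zone = integer(), entry_idx = integer(),
                      exit_idx = integer(), entry_time = numeric(),
                      exit_time = numeric(), duration_h = numeric(),
                      centroid_lon = numeric(), centroid_lat = numeric(),
                      scale_km = numeric())
  r <- rle(as.vector(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  z <- 0
  for (i in seq_along(r$values)) {
    if (!r$values[i] || r$lengths[i] < min_run) {
      # runs shorter than min_run do not survive as labels either
      if (r$values[i]) mask[starts[i]:ends[i]] <- FALSE
      next
    }
    z <- z + 1
    a <- starts[i]; b <- ends[i]
    zones[z, ] <- list(z, a, b, path$t[a], path$t[b],
                       (path$t[b] - path$t[a]) / 3600,
                       mean(path$lon[a:b]), mean(path$lat[a:b]), r_star)
  }
  list(mask = mask, zones = zones)
}

#' Map interpolated-path ARS labels back to a trip's original fixes
#'
#' Moving fixes are matched to the nearest interpolated location by position
#' along the path; resting fixes (removed before interpolation) inherit the
#' label of the nearest moving fix in time, since a resting bout sits at the
#' position where the bird stopped.
#'
#' @param moving_trip the moving-only trip passed to [interpolate_path()]
#'   (output of [filter_resting()]).
#' @param path the interpolated path.
#' @param mask logical ARS mask over `path` rows (from [label_ars()]).
#' @return the full trip (all original fixes) as an `fs_trip` with `speed`,
#'   `resting` and `ars` columns, ready for [trip_metrics()].
#' @export
map_ars_to_trip <- function(moving_trip, path, mask) {
  step <- attr(path, "step")
  seg <- sqrt(diff(moving_trip$x)^2 + diff(moving_trip$y)^2)
  s_fix <- c(0, cumsum(seg))
  idx <- pmin(pmax(round(s_fix / step) + 1L, 1L), nrow(path))
  ars_moving <- mask[idx]
  full <- attr(moving_trip, "full_fixes")
  resting <- attr(moving_trip, "resting_mask")
  if (is.null(full)) {                      # trip had no resting fixes removed
    full <- as.data.frame(moving_trip)
    resting <- rep(FALSE, nrow(full))
  }
  ars <- rep(NA, nrow(full))
  ars[!resting] <- ars_moving
  if (any(resting)) {
    t_mov <- as.numeric(full$time[!resting])
    for (j in which(resting)) {
      nearest <- which.min(abs(t_mov - as.numeric(full$time[j])))
      ars[j] <- ars_moving[nearest]
    }
  }
  full$resting <- resting
  full$ars <- ars
  keep_trip_attrs(full, moving_trip)
}

#' Write an FPT spectrum as CSV
#'
#' @param profile an `fs_fpt_profile`.
#' @param path output file.
#' @export
write_fpt_spectrum <- function(profile, path) {
  utils::write.csv(
    data.frame(trip_id = profile$trip_id %||% NA, radius_km = profile$r,
               var_log_fpt = profile$var_log_fpt),
    path, row.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
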