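#' Construct a gridded environmental field
#'
#' A lightweight regular lon/lat raster: a matrix of values (rows = latitude,
#' descending north to south; columns = longitude, ascending) with cell-centre
#' coordinate vectors, a variable name and an optional time window label.
#'
#' @param values numeric matrix, `length(lat)` rows x `length(lon)` columns.
#' @param lon,lat cell-centre coordinates (degrees); `lat` may be given in
#'   any order and is stored descending.
#' @param var variable name (e.g. `"SST"`, `"CHL"`, `"BAT"`).
#' @param time optional time-window label.
#' @return an `fs_raster`.
#' @export
env_raster <- function(values, lon, lat, var = "", time = NULL) {
  stopifnot(is.matrix(values), nrow(values) == length(lat),
            ncol(values) == length(lon))
  if (is.unsorted(rev(lat))) {               # store north-up
    ord <- order(lat, decreasing = TRUE)
    lat <- lat[ord]
    values <- values[ord, , drop = FALSE]
  }
  structure(list(values = values, lon = lon, lat = lat, var = var,
                 time = time),
            class = "fs_raster")
}

#' @export
print.fs_raster <- function(x, ...) {
  cat(sprintf("<fs_raster> %s: %d x %d cells, lon [%.2f, %.2f], lat [%.2f, %.2f]\n",
              x$var, length(x$lat), length(x$lon),
              min(x$lon), max(x$lon), min(x$lat), max(x$lat)))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$lon, b$lon)) && isTRUE(all.equal(a$lat, b$lat))
}

#' Per-cell mean composite of a raster stack
#'
#' Mean over layers ignoring missing values; a cell is missing only where it
#' is missing in every layer.
#'
#' @param stack list of `fs_raster` objects on identical grids.
#' @return an `fs_raster`.
#' @export
composite_mean <- function(stack) {
  stopifnot(length(stack) >= 1)
  for (r in stack[-1]) if (!same_grid(stack[[1]], r))
    stop("all layers must share the same grid")
  arr <- simplify2array(lapply(stack, function(r) r$values))
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1)
  m <- apply(arr, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  env_raster(m, stack[[1]]$lon, stack[[1]]$lat, var = stack[[1]]$var,
             time = "composite")
}

#' Proportional-change gradient of a raster
#'
#' For each cell, PC = (max - min) * 100 / max over the surrounding 3x3
#' window (shrunken at the grid edge), a percentage measure of local spatial
#' change used as a front/slope indicator for SST, CHL and bathymetry. The
#' formula assumes positive values (pass depth magnitude for bathymetry);
#' cells whose window maximum is not positive are set missing.
#'
#' @param raster an `fs_raster` with (mostly) positive values.
#' @return an `fs_raster` of gradient values in percent, named `<var>G`.
#' @export
gradient_pc <- function(raster) {
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    ri <- max(1, i - 1):min(nr, i + 1)
    for (j in seq_len(nc)) {
      w <- v[ri, max(1, j - 1):min(nc, j + 1)]
      if (all(is.na(w))) next
      mx <- max(w, na.rm = TRUE)
      if (mx <= 0) next
      out[i, j] <- (mx - min(w, na.rm = TRUE)) * 100 / mx
    }
  }
  env_raster(out, raster$lon, raster$lat, var = paste0(raster$var, "G"),
             time = raster$time)
}

#' Distance-to-colony raster
#'
#' Great-circle (WGS84 geodesic) distance from every cell centre to the
#' colony, in km.
#'
#' @param grid list with `lon`, `lat` cell-centre vectors (e.g. from
#'   [ud_grid()] or an existing raster).
#' @param colony `c(lon, lat)`.
#' @return an `fs_raster` named `"DCOL"`.
#' @export
distance_to_colony <- function(grid, colony) {
  cc <- expand.grid(lon = grid$lon, lat = sort(grid$lat, decreasing = TRUE))
  d <- geo_dist_km(cc$lon, cc$lat, colony[1], colony[2])
  env_raster(matrix(d, nrow = length(grid$lat), byrow = TRUE),
             grid$lon, sort(grid$lat, decreasing = TRUE), var = "DCOL")
}

#' SST anomaly relative to a baseline field
#'
#' Per-cell difference `raster - baseline`. The baseline is normally the
#' multi-year mean composite over the study years (see [run_pipeline()]),
#' but any raster on the same grid can be supplied.
#'
#' @param raster,baseline `fs_raster` objects on identical grids.
#' @return an `fs_raster` named `"ASST"` (or `<var>A`).
#' @export
sst_anomaly <- function(raster, baseline) {
  if (!same_grid(raster, baseline)) stop("raster and baseline grids differ")
  env_raster(raster$values - baseline$values, raster$lon, raster$lat,
             var = if (raster$var == "SST") "ASST" else paste0(raster$var, "A"),
             time = raster$time)
}

#' Extract raster values at points
#'
#' Nearest-cell lookup for each point; points outside the grid get NA (the
#' count is reported in a warning).
#'
#' @param raster an `fs_raster`.
#' @param lon,lat point coordinates.
#' @return numeric vector of cell values.
#' @export
extract_at_points <- function(raster, lon, lat) {
  half <- if (length(raster$lon) > 1) diff(raster$lon[1:2]) / 2 else Inf
  i <- vapply(lat, function(p) which.min(abs(raster$lat - p)), integer(1))
  j <- vapply(lon, function(p) which.min(abs(raster$lon - p)), integer(1))
  out <- raster$values[cbind(i, j)]
  off <- abs(raster$lat[i] - lat) > 2 * abs(half) |
    abs(raster$lon[j] - lon) > 2 * abs(half)
  if (any(off)) {
    out[off] <- NA_real_
    warning(sum(off), " points outside the raster grid")
  }
  out
}

#' Mean raster value within a great-circle buffer
#'
#' Mean over cells whose centre lies within `buffer_km` of `center`
#' (default: the 200-km colony buffer used for the regional environmental
#' summaries; configurable because narrower coastal buffers are also used).
#'
#' @param raster an `fs_raster`.
#' @param center `c(lon, lat)`.
#' @param buffer_km buffer radius (km).
#' @return mean of non-missing cell values within the buffer.
#' @export
buffer_mean <- function(raster, center, buffer_km = 200) {
  cc <- expand.grid(lon = raster$lon, lat = raster$lat)
  d <- geo_dist_km(cc$lon, cc$lat, center[1], center[2])
  # expand.grid: lon varies fastest, so fill by row
  keep <- matrix(d <= buffer_km, nrow = length(raster$lat), byrow = TRUE)
  mean(raster$values[keep], na.rm = TRUE)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text single-band georeferenced grid (north-up, WGS84 lon/lat).
#'
#' @param raster an `fs_raster`.
#' @param path output file.
#' @param na_value NODATA value written for missing cells.
#' @export
write_ascii_grid <- function(raster, path, na_value = -9999) {
  cell <- if (length(raster$lon) > 1) diff(raster$lon[1:2]) else
    diff(raster$lat[1:2]) * -1
  if (length(raster$lat) > 1 &&
      abs(abs(diff(raster$lat[1:2])) - cell) > 1e-9)
    stop("ESRI ASCII grids require square cells")
  v <- raster$values
  v[is.na(v)] <- na_value
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", min(raster$lon) - cell / 2),
    sprintf("yllcorner %.10g", min(raster$lat) - cell / 2),
    sprintf("cellsize %.10g", cell),
    sprintf("NODATA_value %g", na_value)
  ), con)
  utils::write.table(format(v, trim = TRUE, digits = 8), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @param var variable name to attach.
#' @return an `fs_raster`.
#' @export
read_ascii_grid <- function(path, var = "") {
  hdr <- utils::read.table(path, nrows = 6, stringsAsFactors = FALSE)
  h <- stats::setNames(as.numeric(hdr[[2]]), tolower(hdr[[1]]))
  v <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(v) <- NULL
  v[v == h[["nodata_value"]]] <- NA
  cell <- h[["cellsize"]]
  lon <- h[["xllcorner"]] + cell * (seq_len(h[["ncols"]]) - 0.5)
  lat <- h[["yllcorner"]] + cell * (rev(seq_len(h[["nrows"]])) - 0.5)
  env_raster(v, lon, lat, var = var)
}
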