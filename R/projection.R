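#' Lambert azimuthal equal-area projection centred on the colony
#'
#' Projects longitude/latitude (WGS84 decimal degrees) onto a planar
#' azimuthal equal-area coordinate system in kilometres, centred on an
#' arbitrary point (normally the breeding colony). The sphere radius is the
#' Gaussian mean radius of curvature at the centre latitude, which keeps
#' planar distances within 0.5% of WGS84 geodesic distances out to ~1000 km
#' from the centre.
#'
#' @param lon,lat numeric vectors of coordinates (decimal degrees).
#' @param center numeric length-2 vector `c(lon, lat)` of the projection
#'   centre.
#' @return a data.frame with columns `x`, `y` (km east/north of the centre).
#' @seealso [laea_inverse()]
#' @export
laea_project <- function(lon, lat, center) {
  stopifnot(length(center) == 2, all(is.finite(center)))
  if (any(abs(lat) > 90, na.rm = TRUE) || any(abs(lon) > 180, na.rm = TRUE))
    stop("coordinates out of range: |lat| <= 90 and |lon| <= 180 required")
  R <- gaussian_radius_km(center[2])
  lam0 <- center[1] * pi / 180
  phi0 <- center[2] * pi / 180
  lam <- lon * pi / 180
  phi <- lat * pi / 180
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  if (any(denom < 1e-9, na.rm = TRUE))
    stop("point (anti)podal to projection center: projection undefined")
  kp <- sqrt(2 / denom)
  data.frame(
    x = R * kp * cos(phi) * sin(lam - lam0),
    y = R * kp * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  )
}

#' Inverse Lambert azimuthal equal-area projection
#'
#' @param x,y planar coordinates in km as produced by [laea_project()].
#' @param center the same centre passed to [laea_project()].
#' @return data.frame with columns `lon`, `lat` (decimal degrees).
#' @export
laea_inverse <- function(x, y, center) {
  R <- gaussian_radius_km(center[2])
  lam0 <- center[1] * pi / 180
  phi0 <- center[2] * pi / 180
  rho <- sqrt(x^2 + y^2)
  out <- data.frame(lon = rep(center[1], length(x)), lat = rep(center[2], length(x)))
  nz <- which(rho > 1e-12)
  if (length(nz)) {
    c_ang <- 2 * asin(pmin(1, rho[nz] / (2 * R)))
    phi <- asin(cos(c_ang) * sin(phi0) +
                  y[nz] * sin(c_ang) * cos(phi0) / rho[nz])
    lam <- lam0 + atan2(x[nz] * sin(c_ang),
                        rho[nz] * cos(phi0) * cos(c_ang) -
                          y[nz] * sin(phi0) * sin(c_ang))
    out$lon[nz] <- lam * 180 / pi
    out$lat[nz] <- phi * 180 / pi
  }
  out
}

# Gaussian mean radius of curvature sqrt(M*N) on WGS84 at latitude phi (deg)
gaussian_radius_km <- function(lat_deg) {
  a <- 6378.137
  e2 <- 0.00669437999014
  s2 <- sin(lat_deg * pi / 180)^2
  W <- sqrt(1 - e2 * s2)
  M <- a * (1 - e2) / W^3
  N <- a / W
  sqrt(M * N)
}

#' WGS84 geodesic distance in kilometres
#'
#' Thin wrapper over [geosphere::distGeo()] returning km; used for all
#' colony-distance and speed computations so reported ranges are ellipsoidal
#' rather than planar.
#'
#' @param lon1,lat1,lon2,lat2 coordinate vectors (decimal degrees).
#' @return numeric vector of distances (km).
#' @export
geo_dist_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distGeo(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}
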