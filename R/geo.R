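# Geodetic helpers shared across modules: a local azimuthal-equidistant
# projection for planar Kalman/KDE math, great-circle distances for
# everything that is reported in km, solar geometry for diel assignment,
# and point-in-polygon membership for ecoregion assignment.

EARTH_RADIUS_KM <- 6371.0088

#' Project lon/lat to a local azimuthal equidistant plane
#'
#' Spherical azimuthal equidistant projection centred on `origin`.
#' Distances from the origin are exact; distortion grows slowly away from
#' it, which is adequate for trips of a few thousand km. Used for the
#' track smoother and kernel density estimation; reported distances are
#' always recomputed geodesically.
#'
#' @param lon,lat numeric vectors of coordinates (decimal degrees, WGS84).
#' @param origin length-2 numeric `c(lon, lat)` of the projection centre.
#' @return matrix with columns `x`, `y` in km.
#' @export
project_aeqd <- function(lon, lat, origin) {
  phi  <- lat * pi / 180
  lam  <- lon * pi / 180
  phi0 <- origin[2] * pi / 180
  lam0 <- origin[1] * pi / 180
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  cosc <- pmin(1, pmax(-1, cosc))
  c    <- acos(cosc)
  az   <- atan2(cos(phi) * sin(lam - lam0),
                cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  k    <- EARTH_RADIUS_KM * c
  cbind(x = k * sin(az), y = k * cos(az))
}

#' Inverse of [project_aeqd()]
#'
#' @param x,y numeric vectors in km.
#' @param origin length-2 numeric `c(lon, lat)`.
#' @return matrix with columns `lon`, `lat` in decimal degrees.
#' @export
unproject_aeqd <- function(x, y, origin) {
  phi0 <- origin[2] * pi / 180
  lam0 <- origin[1] * pi / 180
  rho  <- sqrt(x^2 + y^2)
  c    <- rho / EARTH_RADIUS_KM
  phi  <- ifelse(rho < 1e-12, phi0,
                 asin(pmin(1, pmax(-1, cos(c) * sin(phi0) +
                                     y * sin(c) * cos(phi0) / pmax(rho, 1e-12)))))
  lam  <- ifelse(rho < 1e-12, lam0,
                 lam0 + atan2(x * sin(c),
                              rho * cos(phi0) * cos(c) - y * sin(phi0) * sin(c)))
  cbind(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

#' Great-circle distance between successive positions
#'
#' @param lon,lat coordinate vectors (length n >= 2).
#' @return numeric vector of length n - 1, km (haversine).
#' @export
gc_step_km <- function(lon, lat) {
  n <- length(lon)
  stopifnot(n >= 2, length(lat) == n)
  geosphere::distHaversine(cbind(lon[-n], lat[-n]), cbind(lon[-1], lat[-1])) / 1000
}

# Inner turning angle (degrees) at position i of the triple (i-1, i, i+1):
# 180 means dead straight, small values a sharp spike.
turning_angle_deg <- function(lon, lat) {
  n <- length(lon)
  if (n < 3) return(numeric(0))
  b_in  <- geosphere::bearing(cbind(lon[1:(n - 2)], lat[1:(n - 2)]),
                              cbind(lon[2:(n - 1)], lat[2:(n - 1)]))
  b_out <- geosphere::bearing(cbind(lon[2:(n - 1)], lat[2:(n - 1)]),
                              cbind(lon[3:n],       lat[3:n]))
  turn <- abs(((b_out - b_in) + 180) %% 360 - 180)
  180 - turn
}

#' Solar zenith angle
#'
#' NOAA's general solar-position approximation (fractional-year Fourier
#' series for declination and the equation of time). Accurate to well
#' under a degree, which is ample for a day/night split.
#'
#' @param time POSIXct (UTC) vector.
#' @param lat,lon position in decimal degrees.
#' @return zenith angle in degrees (0 = sun overhead, > 90 = below horizon).
#' @export
solar_zenith <- function(time, lat, lon) {
  lt   <- as.POSIXlt(time, tz = "UTC")
  doy  <- lt$yday + 1
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  g <- 2 * pi / 365 * (doy - 1 + (hour - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g)
                      - 0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- (0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g)
           - 0.006758 * cos(2 * g) + 0.000907 * sin(2 * g)
           - 0.002697 * cos(3 * g) + 0.00148 * sin(3 * g))
  tst <- hour * 60 + eqtime + 4 * lon        # true solar time, minutes
  ha  <- (tst / 4 - 180) * pi / 180          # hour angle, radians
  phi <- lat * pi / 180
  cosz <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha)
  acos(pmin(1, pmax(-1, cosz))) * 180 / pi
}

# Point-in-polygon membership. `poly` is a data.frame/matrix with columns
# lon, lat describing a single (optionally closed) ring.
points_in_polygon <- function(lon, lat, poly) {
  poly <- as.matrix(poly[, c("lon", "lat")])
  # mgcv::in.out wants an unclosed boundary matrix
  if (nrow(poly) > 1 && all(poly[1, ] == poly[nrow(poly), ]))
    poly <- poly[-nrow(poly), , drop = FALSE]
  mgcv::in.out(poly, cbind(lon, lat))
}
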