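# Spherical geometry on the authalic radius used throughout the package.

#' Earth radius (km)
#'
#' Authalic sphere radius used for all great-circle arithmetic in the
#' package, 6371.0088 km.
#' @export
EARTH_RADIUS_KM <- 6371.0088

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Great-circle distance by the haversine formula
#'
#' Distance in km between points on a sphere of radius
#' [EARTH_RADIUS_KM]. All arguments recycle to a common length.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Numeric vector of distances in km.
#' @examples
#' haversine_km(0, 0, 0, 1)   # one degree of latitude, ~111.2 km
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  p1 <- .deg2rad(lat1); p2 <- .deg2rad(lat2)
  dp <- p2 - p1
  dl <- .deg2rad(lon2 - lon1)
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Initial great-circle bearing
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Bearing in degrees clockwise from north, in [0, 360).
#' @export
bearing_deg <- function(lon1, lat1, lon2, lat2) {
  p1 <- .deg2rad(lat1); p2 <- .deg2rad(lat2)
  dl <- .deg2rad(lon2 - lon1)
  y <- sin(dl) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl)
  (.rad2deg(atan2(y, x))) %% 360
}

#' Destination point along a great circle
#'
#' @param lon,lat Start coordinates in decimal degrees.
#' @param bearing Initial bearing in degrees clockwise from north.
#' @param dist_km Distance travelled in km.
#' @return A list with components `lon` and `lat` (degrees, lon wrapped
#'   to \[-180, 180)).
#' @export
destination_point <- function(lon, lat, bearing, dist_km) {
  d <- dist_km / EARTH_RADIUS_KM
  p1 <- .deg2rad(lat); l1 <- .deg2rad(lon); b <- .deg2rad(bearing)
  p2 <- asin(sin(p1) * cos(d) + cos(p1) * sin(d) * cos(b))
  l2 <- l1 + atan2(sin(b) * sin(d) * cos(p1),
                   cos(d) - sin(p1) * sin(p2))
  list(lon = wrap_lon(.rad2deg(l2)), lat = .rad2deg(p2))
}

#' Wrap longitudes to [-180, 180)
#' @param lon Longitudes in degrees.
#' @export
wrap_lon <- function(lon) ((lon + 180) %% 360) - 180

#' Interpolate along a great circle
#'
#' Points at fractions `f` of the way from point 1 to point 2 along the
#' connecting great circle.
#'
#' @param lon1,lat1,lon2,lat2 End points in degrees (scalars).
#' @param f Numeric vector of fractions in \[0, 1\].
#' @return data.frame with columns `lon`, `lat`.
#' @export
gc_interpolate <- function(lon1, lat1, lon2, lat2, f) {
  p1 <- .deg2rad(lat1); l1 <- .deg2rad(lon1)
  p2 <- .deg2rad(lat2); l2 <- .deg2rad(lon2)
  d <- haversine_km(lon1, lat1, lon2, lat2) / EARTH_RADIUS_KM
  if (d < 1e-12) {
    return(data.frame(lon = rep(lon1, length(f)), lat = rep(lat1, length(f))))
  }
  a <- sin((1 - f) * d) / sin(d)
  b <- sin(f * d) / sin(d)
  x <- a * cos(p1) * cos(l1) + b * cos(p2) * cos(l2)
  y <- a * cos(p1) * sin(l1) + b * cos(p2) * sin(l2)
  z <- a * sin(p1) + b * sin(p2)
  data.frame(lon = wrap_lon(.rad2deg(atan2(y, x))),
             lat = .rad2deg(atan2(z, sqrt(x^2 + y^2))))
}

# Ray-casting point-in-polygon test; polygon as data.frame(lon, lat),
# implicitly closed. Treats coordinates as planar (adequate for the
# compact synthetic land masses used here).
point_in_polygon <- function(lon, lat, poly) {
  n <- nrow(poly)
  px <- poly$lon; py <- poly$lat
  inside <- rep(FALSE, length(lon))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > lat) != (py[j] > lat)) &
      (lon < (px[j] - px[i]) * (lat - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

# Densify a polyline/polygon boundary so consecutive vertices are at
# most `spacing_km` apart (great-circle). Returns data.frame(lon, lat).
densify_boundary <- function(poly, spacing_km = 5, closed = TRUE) {
  n <- nrow(poly)
  idx <- if (closed) c(seq_len(n), 1L) else seq_len(n)
  out <- vector("list", length(idx) - 1L)
  for (k in seq_len(length(idx) - 1L)) {
    i <- idx[k]; j <- idx[k + 1L]
    d <- haversine_km(poly$lon[i], poly$lat[i], poly$lon[j], poly$lat[j])
    m <- max(1L, ceiling(d / spacing_km))
    f <- seq(0, 1, length.out = m + 1L)[-(m + 1L)]
    out[[k]] <- gc_interpolate(poly$lon[i], poly$lat[i],
                               poly$lon[j], poly$lat[j], f)
  }
  do.call(rbind, out)
}
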