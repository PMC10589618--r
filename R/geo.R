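# Spherical geometry primitives shared by all spatial stages.
# All computations use a sphere of mean radius 6371.0088 km; bearings are
# degrees clockwise from true north; longitudes are normalised to [-180, 180).

#' Mean Earth radius (km) used throughout the package
#' @export
EARTH_RADIUS_KM <- 6371.0088

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Normalise longitudes to the half-open interval [-180, 180)
#' @param lon longitudes in degrees.
#' @return numeric vector in [-180, 180).
#' @export
normalize_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}

#' Great-circle distance between points (haversine)
#'
#' Vectorised haversine distance on a sphere of radius 6371.0088 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return distance in km.
#' @examples
#' great_circle_km(0, 0, 0, 1)   # ~111.195 km, one degree along the equator
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(lat1) <= 90), all(abs(lat2) <= 90))
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dp <- p2 - p1
  dl <- deg2rad(lon2 - lon1)
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Initial great-circle bearing from one point toward another
#'
#' @inheritParams great_circle_km
#' @return bearing in degrees clockwise from true north, in [0, 360).
#'   Coincident points have no bearing and raise an error.
#' @export
initial_bearing <- function(lat1, lon1, lat2, lon2) {
  if (any(lat1 == lat2 & normalize_lon(lon1) == normalize_lon(lon2))) {
    stop("bearing undefined for coincident points")
  }
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dl <- deg2rad(lon2 - lon1)
  y <- sin(dl) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl)
  (rad2deg(atan2(y, x))) %% 360
}

#' Destination point along a great circle
#'
#' Moves `d_km` from (`lat`, `lon`) along initial bearing `bearing_deg`.
#'
#' @param lat,lon start point, decimal degrees.
#' @param bearing_deg initial bearing, degrees clockwise from north.
#' @param d_km distance in km.
#' @return list with elements `lat`, `lon` (degrees; lon in [-180, 180)).
#' @export
destination_point <- function(lat, lon, bearing_deg, d_km) {
  p1 <- deg2rad(lat); l1 <- deg2rad(lon)
  th <- deg2rad(bearing_deg)
  dr <- d_km / EARTH_RADIUS_KM
  p2 <- asin(sin(p1) * cos(dr) + cos(p1) * sin(dr) * cos(th))
  l2 <- l1 + atan2(sin(th) * sin(dr) * cos(p1),
                   cos(dr) - sin(p1) * sin(p2))
  list(lat = rad2deg(p2), lon = normalize_lon(rad2deg(l2)))
}

#' Fold the difference of two angles into [0, 180]
#'
#' The unsigned angular separation of two directions, as used for relative
#' wind direction (0 = aligned, 180 = opposed).
#'
#' @param a,b angles in degrees (any real values).
#' @return folded difference in degrees, in [0, 180].
#' @export
fold_angle_0_180 <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# Signed smallest rotation from angle a to angle b, in (-180, 180].
signed_angle_diff <- function(a, b) {
  d <- (b - a) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Build a tiling set of sectors around an origin
#'
#' Constructs `360/aperture` sectors of equal aperture around an origin point.
#' The first (focal) sector is centred on `focal_bearing`; the rest tile the
#' full circle at multiples of the aperture. Sector membership uses a
#' half-open bearing rule [centre - aperture/2, centre + aperture/2) so the
#' sectors partition the disc.
#'
#' @param lat,lon origin in decimal degrees.
#' @param focal_bearing centre bearing of the focal sector, degrees.
#' @param aperture sector aperture in degrees; must divide 360 evenly.
#' @param radius_km sector radius in km.
#' @return data.frame with one row per sector: `sector_index`,
#'   `center_bearing`, `is_focal`, plus origin/aperture/radius columns.
#' @export
make_sectors <- function(lat, lon, focal_bearing, aperture = 60,
                         radius_km = 2000) {
  if (360 %% aperture != 0) stop("aperture must divide 360 evenly")
  n <- 360 %/% aperture
  centers <- (focal_bearing + aperture * (seq_len(n) - 1)) %% 360
  data.frame(
    sector_index = seq_len(n),
    lat = lat, lon = lon,
    center_bearing = centers,
    aperture = aperture,
    radius_km = radius_km,
    is_focal = seq_len(n) == 1L
  )
}

#' Test whether points fall inside one sector
#'
#' A point is inside iff its great-circle distance from the sector origin is
#' at most the radius and the folded bearing offset from the centre bearing
#' is within the half-open interval [-aperture/2, aperture/2). The origin
#' itself (distance 0, bearing undefined) belongs to the focal sector by
#' convention.
#'
#' @param sector one row of [make_sectors()].
#' @param lat,lon point coordinates (vectorised).
#' @return logical vector.
#' @export
point_in_sector <- function(sector, lat, lon) {
  d <- great_circle_km(sector$lat, sector$lon, lat, lon)
  at_origin <- d < 1e-9
  inside <- logical(length(d))
  if (any(!at_origin)) {
    b <- initial_bearing(sector$lat, sector$lon, lat[!at_origin],
                         lon[!at_origin])
    off <- signed_angle_diff(sector$center_bearing, b)
    inside[!at_origin] <- d[!at_origin] <= sector$radius_km &
      off >= -sector$aperture / 2 & off < sector$aperture / 2
  }
  inside[at_origin] <- isTRUE(sector$is_focal) & d[at_origin] <= sector$radius_km
  inside
}

#' Stereographic-style polar grid around an origin
#'
#' Cell centres lie at the midpoints of `n_r` equal-width radial bands and
#' `n_theta` equal azimuthal steps. Cell areas are exact spherical areas:
#' the area of each radial band (difference of spherical caps) divided by
#' `n_theta`, so the areas sum to the spherical-cap area of the disc by
#' construction.
#'
#' @param lat,lon origin in decimal degrees.
#' @param radius_km disc radius (km); radii above 10,000 km are rejected.
#' @param n_r,n_theta number of radial / azimuthal divisions (>= 1).
#' @return data.frame with `r_km`, `theta_deg` (bearing of cell centre),
#'   `lat`, `lon` (cell centre), `area_km2`.
#' @export
polar_grid <- function(lat, lon, radius_km = 2000, n_r = 100, n_theta = 120) {
  stopifnot(n_r >= 1, n_theta >= 1)
  if (radius_km > 10000) stop("radius above 10,000 km not supported")
  r_edges <- seq(0, radius_km, length.out = n_r + 1)
  r_mid <- (r_edges[-1] + r_edges[-(n_r + 1)]) / 2
  th <- (seq_len(n_theta) - 0.5) * (360 / n_theta)
  R <- EARTH_RADIUS_KM
  band_area <- 2 * pi * R^2 *
    (cos(r_edges[-(n_r + 1)] / R) - cos(r_edges[-1] / R))
  g <- expand.grid(r_km = r_mid, theta_deg = th)
  g$area_km2 <- rep(band_area / n_theta, times = n_theta)
  dest <- destination_point(lat, lon, g$theta_deg, g$r_km)
  g$lat <- dest$lat
  g$lon <- dest$lon
  attr(g, "origin") <- c(lat = lat, lon = lon)
  attr(g, "radius_km") <- radius_km
  g
}

#' Spherical-cap area of a disc of given great-circle radius
#' @param radius_km disc radius in km.
#' @return area in km^2.
#' @export
cap_area_km2 <- function(radius_km) {
  2 * pi * EARTH_RADIUS_KM^2 * (1 - cos(radius_km / EARTH_RADIUS_KM))
}

#' Export sectors as GeoJSON polygons
#'
#' Each sector boundary arc is densified in 1-degree bearing steps for
#' inspection in standard GIS viewers.
#'
#' @param sectors data.frame from [make_sectors()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
sectors_to_geojson <- function(sectors, file) {
  features <- lapply(seq_len(nrow(sectors)), function(i) {
    s <- sectors[i, ]
    b <- seq(s$center_bearing - s$aperture / 2,
             s$center_bearing + s$aperture / 2, by = 1)
    arc <- destination_point(s$lat, s$lon, b %% 360, s$radius_km)
    coords <- rbind(c(s$lon, s$lat), cbind(arc$lon, arc$lat),
                    c(s$lon, s$lat))
    list(
      type = "Feature",
      properties = list(sector_index = s$sector_index,
                        center_bearing = s$center_bearing,
                        is_focal = s$is_focal),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(coords)),
                                                function(k) coords[k, ])))
    )
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, file, auto_unbox = TRUE, digits = 8)
  invisible(file)
}
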