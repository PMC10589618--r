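# Gridded 10 m wind fields and per-sector wind covariates.
# Wind direction is the vector heading ("direction-to"): the compass
# direction toward which the air moves, so a relative wind direction of 0
# degrees is a pure tailwind for a bird heading along the sector centre and
# 180 degrees a pure headwind.

#' Construct a gridded wind field
#'
#' @param times POSIXct vector of (hourly) time slices.
#' @param lats,lons grid axes in degrees (regular, increasing).
#' @param u,v arrays `[time, lat, lon]` of eastward / northward wind
#'   components at 10 m, m/s.
#' @return object of class `wind_field`.
#' @export
wind_field <- function(times, lats, lons, u, v) {
  stopifnot(all(dim(u) == c(length(times), length(lats), length(lons))),
            all(dim(u) == dim(v)), all(is.finite(u)), all(is.finite(v)))
  structure(list(times = times, lats = lats, lons = lons, u = u, v = v),
            class = "wind_field")
}

bilinear <- function(lats, lons, slice, lat, lon) {
  if (lat < min(lats) || lat > max(lats) || lon < min(lons) || lon > max(lons)) {
    stop("query point outside wind-field coverage")
  }
  i <- findInterval(lat, lats, rightmost.closed = TRUE)
  j <- findInterval(lon, lons, rightmost.closed = TRUE)
  i <- min(max(i, 1), length(lats) - 1)
  j <- min(max(j, 1), length(lons) - 1)
  fx <- (lat - lats[i]) / (lats[i + 1] - lats[i])
  fy <- (lon - lons[j]) / (lons[j + 1] - lons[j])
  (1 - fx) * (1 - fy) * slice[i, j] + fx * (1 - fy) * slice[i + 1, j] +
    (1 - fx) * fy * slice[i, j + 1] + fx * fy * slice[i + 1, j + 1]
}

#' Wind at a point and time
#'
#' Bilinear interpolation in space at the nearest time slice.
#'
#' @param field a [wind_field()].
#' @param lat,lon query point, degrees.
#' @param time POSIXct query time (must be within the field's span +- one
#'   slice spacing).
#' @return list with `u`, `v`, `speed` (m/s) and `direction_to` (degrees
#'   clockwise from north, the heading of the air).
#' @export
wind_at <- function(field, lat, lon, time) {
  dt <- abs(as.numeric(field$times) - as.numeric(time))
  ti <- which.min(dt)
  u <- bilinear(field$lats, field$lons, field$u[ti, , ], lat, lon)
  v <- bilinear(field$lats, field$lons, field$v[ti, , ], lat, lon)
  list(u = u, v = v, speed = sqrt(u^2 + v^2),
       direction_to = (rad2deg(atan2(u, v))) %% 360)
}

#' Relative wind direction for a sector
#'
#' Folded angular difference between the sector centre bearing and the wind
#' heading: 0 = tailwind, 180 = headwind.
#'
#' @param center_bearing sector centre bearing, degrees.
#' @param wind result of [wind_at()] (or any list with `direction_to`).
#' @return degrees in [0, 180].
#' @export
relative_wind_direction <- function(center_bearing, wind) {
  fold_angle_0_180(center_bearing, wind$direction_to)
}

#' Wind speed at a decision point
#'
#' Evaluated once at the decision-point fix; shared by all six sectors of
#' the stratum (wind speed does not vary within a choice set).
#'
#' @param field a [wind_field()].
#' @param dp a `decision_point`.
#' @return speed in m/s.
#' @export
stratum_wind_speed <- function(field, dp) {
  wind_at(field, dp$lat, dp$lon, dp$time)$speed
}

#' Write a wind field as a plain-text grid file
#' @param field a [wind_field()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_wind_csv <- function(field, file) {
  g <- expand.grid(time = format(field$times, "%Y-%m-%dT%H:%M:%SZ",
                                 tz = "UTC"),
                   lat = field$lats, lon = field$lons,
                   stringsAsFactors = FALSE)
  g$u10 <- as.vector(field$u)
  g$v10 <- as.vector(field$v)
  utils::write.csv(g, file, row.names = FALSE)
  invisible(file)
}

#' Read a wind field written by [write_wind_csv()]
#' @param file path.
#' @return a [wind_field()].
#' @export
read_wind_csv <- function(file) {
  g <- utils::read.csv(file)
  times <- sort(unique(as.POSIXct(g$time, format = "%Y-%m-%dT%H:%M:%SZ",
                                  tz = "UTC")))
  lats <- sort(unique(g$lat)); lons <- sort(unique(g$lon))
  idx <- cbind(match(as.POSIXct(g$time, format = "%Y-%m-%dT%H:%M:%SZ",
                                tz = "UTC"), times),
               match(g$lat, lats), match(g$lon, lons))
  u <- array(NA_real_, c(length(times), length(lats), length(lons)))
  v <- u
  u[idx] <- g$u10
  v[idx] <- g$v10
  wind_field(times, lats, lons, u, v)
}
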