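# Trip definition, colony-buffer filtering, flight-bout extraction and
# decision-point construction.

#' Split a track into foraging trips
#'
#' A trip starts at the first fix at least `depart_km` from the colony and
#' ends at the first fix following return to the colony (the first fix back
#' within `depart_km` is included as the trip's final fix).
#'
#' @param track data.frame with `lat`, `lon` (one bird, ordered in time).
#' @param colony_lat,colony_lon colony coordinates, degrees.
#' @param depart_km departure threshold in km.
#' @return list of data.frames (one per trip, rows of `track` with original
#'   row indices in attribute `rows`); empty list if the bird never departs.
#' @export
define_trips <- function(track, colony_lat, colony_lon, depart_km = 10) {
  d <- great_circle_km(colony_lat, colony_lon, track$lat, track$lon)
  n <- length(d)
  trips <- list()
  i <- 1
  while (i <= n) {
    start <- NA
    while (i <= n) {
      if (d[i] >= depart_km) { start <- i; break }
      i <- i + 1
    }
    if (is.na(start)) break
    end <- n
    j <- start
    while (j <= n) {
      if (d[j] < depart_km) { end <- j; break }  # first fix following return
      j <- j + 1
    }
    trip <- track[start:end, , drop = FALSE]
    attr(trip, "rows") <- start:end
    trips[[length(trips) + 1]] <- trip
    i <- end + 1
  }
  trips
}

#' Total great-circle path length of a trip (km)
#' @param trip data.frame with `lat`, `lon`.
#' @return path length in km.
#' @export
trip_path_km <- function(trip) {
  n <- nrow(trip)
  if (n < 2) return(0)
  sum(great_circle_km(trip$lat[-n], trip$lon[-n], trip$lat[-1], trip$lon[-1]))
}

#' Retain the longest trip
#'
#' Maximal total path length; ties go to the earliest-starting trip.
#'
#' @param trips list from [define_trips()].
#' @return the selected trip.
#' @export
select_longest_trip <- function(trips) {
  if (length(trips) == 0) stop("no trips to select from")
  lens <- vapply(trips, trip_path_km, numeric(1))
  trips[[which.max(lens)]]  # which.max returns the first (earliest) maximum
}

#' Remove leading/trailing fixes near the colony shelf
#'
#' Drops fixes within `buffer_km` of the shelf centre from the beginning and
#' the end of the trip only; interior fixes are kept even if they re-enter
#' the buffer.
#'
#' @param trip data.frame with `lat`, `lon`.
#' @param shelf_lat,shelf_lon shelf centre, degrees.
#' @param buffer_km buffer radius in km.
#' @return the filtered trip (possibly empty, with a warning).
#' @export
filter_colony_buffer <- function(trip, shelf_lat, shelf_lon, buffer_km = 10) {
  d <- great_circle_km(shelf_lat, shelf_lon, trip$lat, trip$lon)
  inside <- d < buffer_km
  if (all(inside)) {
    warning("entire trip within the shelf buffer; returning empty trip")
    return(trip[0, , drop = FALSE])
  }
  first_keep <- which(!inside)[1]
  last_keep <- max(which(!inside))
  trip[first_keep:last_keep, , drop = FALSE]
}

#' Extract qualifying directed-flight bouts
#'
#' Maximal contiguous runs of `travel` behaviour whose within-bout path
#' length is at least `min_km` and which are immediately preceded by a
#' search or rest fix. Runs starting at the first fix of the trip have no
#' preceding non-travel fix and are excluded.
#'
#' @param trip data.frame with `lat`, `lon` and a `behavior` column with
#'   values in `travel`, `search`, `rest`.
#' @param min_km minimum within-bout cumulative path length, km.
#' @return data.frame with one row per retained bout: `start`, `end` (row
#'   indices into `trip`), `path_km`.
#' @export
extract_flight_bouts <- function(trip, min_km = 20) {
  stopifnot("behavior" %in% names(trip))
  b <- trip$behavior
  r <- rle(b == "travel")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- data.frame(start = integer(0), end = integer(0),
                    path_km = numeric(0))
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    s <- starts[k]; e <- ends[k]
    if (s == 1) next                     # no preceding search/rest period
    seg <- trip[s:e, , drop = FALSE]
    len <- trip_path_km(seg)
    if (len >= min_km) {
      out <- rbind(out, data.frame(start = s, end = e, path_km = len))
    }
  }
  out
}

#' Build a decision point from a flight bout
#'
#' The decision point is the first fix of the bout; its bearing is the
#' initial bearing from the first to the second fix; the focal sector is
#' centred on that bearing and five alternatives tile the rest of the
#' circle.
#'
#' @param trip trip data.frame (with `lat`, `lon`, optional `time`,
#'   `bird_id`).
#' @param bout one row of [extract_flight_bouts()].
#' @param radius_km sector radius, km.
#' @param aperture sector aperture, degrees.
#' @return list of class `decision_point` with fields `bird_id`, `lat`,
#'   `lon`, `time`, `bearing`, `sectors`, `excluded`, `reason`; `NULL` (with
#'   a warning) if the first two fixes coincide.
#' @export
build_decision_point <- function(trip, bout, radius_km = 2000, aperture = 60) {
  s <- bout$start
  if (s + 1 > nrow(trip)) {
    warning("bout too short to compute a bearing; skipped")
    return(NULL)
  }
  if (trip$lat[s] == trip$lat[s + 1] && trip$lon[s] == trip$lon[s + 1]) {
    warning("coincident fixes at bout start; skipped")
    return(NULL)
  }
  bearing <- initial_bearing(trip$lat[s], trip$lon[s],
                             trip$lat[s + 1], trip$lon[s + 1])
  structure(list(
    bird_id = if (!is.null(trip$bird_id)) trip$bird_id[s] else NA,
    lat = trip$lat[s], lon = trip$lon[s],
    time = if (!is.null(trip$time)) trip$time[s] else NA,
    bearing = bearing,
    sectors = make_sectors(trip$lat[s], trip$lon[s], bearing,
                           aperture = aperture, radius_km = radius_km),
    excluded = FALSE, reason = NA_character_
  ), class = "decision_point")
}

#' Flag decision points whose sectors are truncated by land
#'
#' Samples the sector disc on a polar grid and flags the decision point if
#' any grid cell falls on land, since land truncates the over-water reach of
#' some sector below the nominal radius.
#'
#' @param dp a `decision_point`.
#' @param is_land function(lat, lon) -> logical, the land mask.
#' @param n_r,n_theta sampling resolution of the test grid.
#' @return the decision point with `excluded`/`reason` set.
#' @export
exclude_land_truncated <- function(dp, is_land, n_r = 40, n_theta = 60) {
  g <- polar_grid(dp$lat, dp$lon, radius_km = dp$sectors$radius_km[1],
                  n_r = n_r, n_theta = n_theta)
  if (any(is_land(g$lat, g$lon))) {
    dp$excluded <- TRUE
    dp$reason <- "sector truncated by land within radius"
  }
  dp
}

#' Decision points as a flat data.frame
#' @param dps list of `decision_point` objects.
#' @return data.frame, one row per decision point.
#' @export
decision_points_df <- function(dps) {
  do.call(rbind, lapply(dps, function(dp) {
    data.frame(bird_id = dp$bird_id,
               time = if (inherits(dp$time, "POSIXct"))
                 format(dp$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC") else
                   as.character(dp$time),
               lat = dp$lat, lon = dp$lon, bearing = dp$bearing,
               excluded = dp$excluded, reason = dp$reason)
  }))
}
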