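# Received microbarom sound-pressure fields from the observer's perspective.
# Propagation is a deliberately simple single-path law: geometric spreading
# with a configurable exponent plus a linear dB-per-distance absorption term.
# The analysis needs a spatially structured pressure gradient with realistic
# long-range decay, not full stratospheric-duct acoustics; only the
# propagating (long-range) microbarom component is represented.

#' Received sound-pressure field on a polar grid
#'
#' Each cell receives the sum over sources of
#' `A * (r_ref / r)^spreading_exponent * 10^(-absorption_db * r / (20 * 1000))`
#' where `r` is the great-circle distance (km) from the source to the cell
#' centre, `A` is the source amplitude (Pa at the reference distance
#' `r_ref`), and `absorption_db` is expressed in dB per 1,000 km. Distances
#' below `r_ref` are clamped to `r_ref` (the near field is not modelled).
#'
#' @param sources data.frame with `lat`, `lon`, `amplitude` (Pa at
#'   `r_ref_km`); zero rows give a silent field.
#' @param observer_lat,observer_lon observer position, degrees.
#' @param grid polar grid from [polar_grid()] centred on the observer.
#' @param spreading_exponent geometric spreading exponent (1 = cylindrical-
#'   like amplitude decay, pressure halves per distance doubling).
#' @param absorption_db_per_1000km atmospheric absorption, dB per 1,000 km.
#' @param r_ref_km reference distance at which `amplitude` is defined.
#' @param is_land optional function(lat, lon) -> logical; land cells are
#'   masked to zero pressure (no reception contribution).
#' @return object of class `soundscape_field`: the grid with a `pressure_pa`
#'   column and observer/band attributes.
#' @export
received_field <- function(sources, observer_lat, observer_lon, grid,
                           spreading_exponent = 1,
                           absorption_db_per_1000km = 1,
                           r_ref_km = 100, is_land = NULL,
                           band_hz = c(0.06, 1.0)) {
  if (nrow(sources) > 0 && any(sources$amplitude < 0)) {
    stop("source amplitudes must be non-negative")
  }
  p <- numeric(nrow(grid))
  for (i in seq_len(nrow(sources))) {
    r <- great_circle_km(sources$lat[i], sources$lon[i], grid$lat, grid$lon)
    r <- pmax(r, r_ref_km)
    p <- p + sources$amplitude[i] * (r_ref_km / r)^spreading_exponent *
      10^(-absorption_db_per_1000km * r / 20000)
  }
  if (!is.null(is_land)) p[is_land(grid$lat, grid$lon)] <- 0
  field <- grid
  field$pressure_pa <- p
  attr(field, "observer") <- c(lat = observer_lat, lon = observer_lon)
  attr(field, "band_hz") <- band_hz
  class(field) <- c("soundscape_field", class(field))
  field
}

#' Integrate sound pressure over a sector
#'
#' Area-weighted (un-normalised) sum of cell pressure times spherical cell
#' area over cells whose centres fall in the sector, in Pa km^2. Sector
#' membership uses the cell's polar coordinates directly (the grid and the
#' sectors share the observer origin), with the same half-open bearing rule
#' as [point_in_sector()].
#'
#' @param field a `soundscape_field`.
#' @param sector one row of [make_sectors()]; its origin must be the field
#'   observer.
#' @return integrated sound pressure, Pa km^2.
#' @export
integrate_sector_sp <- function(field, sector) {
  obs <- attr(field, "observer")
  if (great_circle_km(obs["lat"], obs["lon"], sector$lat, sector$lon) > 1e-6) {
    stop("sector origin does not match field observer")
  }
  off <- signed_angle_diff(sector$center_bearing, field$theta_deg)
  inside <- field$r_km <= sector$radius_km &
    off >= -sector$aperture / 2 & off < sector$aperture / 2
  sum(field$pressure_pa[inside] * field$area_km2[inside])
}

#' Integrated sound pressure for every sector of a decision point
#' @param field a `soundscape_field` centred on the decision point.
#' @param sectors data.frame from [make_sectors()].
#' @return numeric vector, one value per sector row.
#' @export
sector_sp <- function(field, sectors) {
  vapply(seq_len(nrow(sectors)), function(i) {
    integrate_sector_sp(field, sectors[i, ])
  }, numeric(1))
}

#' z-standardise the six sector values of one choice set
#'
#' Centres and scales by the sample (n-1) standard deviation within the
#' choice set, absorbing temporal changes in overall soundscape level. A
#' degenerate all-equal set maps to all zeros.
#'
#' @param x numeric vector of sector values (one choice set).
#' @return z-scores with mean 0 and sample s.d. 1 (or all zeros).
#' @export
zstandardize_choice_set <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Match a fix time to the nearest available field time
#'
#' @param time POSIXct fix time.
#' @param field_times sorted POSIXct vector of available field times.
#' @param tol_h tolerance in hours; beyond it no field is matched.
#' @return the matched POSIXct time, or `NULL` if none is within tolerance.
#'   Exact ties between two field times go to the earlier one.
#' @export
match_field_to_fix <- function(time, field_times, tol_h = 1) {
  dt <- abs(as.numeric(field_times) - as.numeric(time))
  i <- which(dt == min(dt))[1]  # earlier of tied neighbours (sorted input)
  if (dt[i] > tol_h * 3600) return(NULL)
  field_times[i]
}

#' Cumulative fraction of integrated sound pressure within radius
#'
#' Diagnostic for how much of the perceived acoustic signal originates
#' within a given range of the observer.
#'
#' @param field a `soundscape_field` (typically built on an extended-radius
#'   grid).
#' @param radii vector of radii (km) at which to evaluate the fraction.
#' @return data.frame with `radius_km` and `fraction` (non-decreasing,
#'   reaching 1 at the grid's maximum radius).
#' @export
power_within_radius <- function(field, radii) {
  total <- sum(field$pressure_pa * field$area_km2)
  frac <- vapply(radii, function(r) {
    if (total == 0) return(NA_real_)
    sum(field$pressure_pa[field$r_km <= r] * field$area_km2[field$r_km <= r]) /
      total
  }, numeric(1))
  data.frame(radius_km = radii, fraction = frac)
}

#' Write a gridded field as a plain-text grid file
#'
#' Long-format CSV with a JSON attribute header line (prefixed `#`), the
#' package's text representation of gridded fields.
#'
#' @param field a `soundscape_field`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_field_csv <- function(field, file) {
  hdr <- jsonlite::toJSON(list(observer = as.list(attr(field, "observer")),
                               band_hz = attr(field, "band_hz")),
                          auto_unbox = TRUE)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  utils::write.csv(as.data.frame(field)[, c("r_km", "theta_deg", "lat",
                                            "lon", "area_km2", "pressure_pa")],
                   con, row.names = FALSE)
  invisible(file)
}

#' Read a gridded field written by [write_field_csv()]
#' @param file path written by [write_field_csv()].
#' @return a `soundscape_field`.
#' @export
read_field_csv <- function(file) {
  first <- readLines(file, n = 1)
  meta <- jsonlite::fromJSON(sub("^# ", "", first))
  df <- utils::read.csv(file, comment.char = "#")
  attr(df, "observer") <- c(lat = meta$observer$lat, lon = meta$observer$lon)
  attr(df, "band_hz") <- meta$band_hz
  class(df) <- c("soundscape_field", class(df))
  df
}
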