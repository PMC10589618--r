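# Synthetic study generator: wind fields, storm-driven microbarom sources,
# state-switching tracks with a known conditional-logit sector-choice law,
# and a fast choice-set generator for calibration studies. Every downstream
# stage of the pipeline can be exercised against the stored ground truth.

#' Simulation configuration
#'
#' Defaults emulate the study conditions: 15-min fixes, three movement
#' states (directed travel, search, rest) with gamma step lengths and von
#' Mises turning angles, a Crozet-like colony, smooth mid-latitude
#' westerlies, and a handful of drifting storm-like microbarom sources.
#' States are ordered 1 = travel, 2 = search, 3 = rest. The travel-state
#' turn concentration (8.5) puts the central 90% of travel turning angles at
#' roughly (-0.56, 0.56) radians, matching the shallow turning that defines
#' directed flight.
#'
#' @param n_birds number of birds.
#' @param n_days days of track per bird.
#' @param fixes_interval_min fix interval, minutes.
#' @param colony_lat,colony_lon colony coordinates, degrees.
#' @param state_params list of per-state lists with `shape`, `scale` (gamma
#'   step length, km per fix), `mu`, `kappa` (von Mises turning angle, rad).
#' @param tpm 3x3 transition probability matrix (rows sum to 1).
#' @param beta_true named selection coefficients on the scaled covariates
#'   (`SP`, `windDir`, `SP:windDir`, `SP:windSp`, `windDir:windSp`).
#' @param storm_params list: `count`, `drift_speed_kmh`, `amplitude_pa`
#'   (source pressure at the reference distance), `scale_km`.
#' @param wind_params list: `mean_speed` (m/s), `corr_scale_km`.
#' @param seed integer seed recorded in all outputs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_birds = 6, n_days = 5, fixes_interval_min = 15,
                       colony_lat = -46.4, colony_lon = 51.77,
                       state_params = list(
                         travel = list(shape = 6, scale = 10 / 6,
                                       mu = 0, kappa = 8.5),
                         search = list(shape = 2, scale = 1.5,
                                       mu = 0, kappa = 0.7),
                         rest = list(shape = 1.5, scale = 0.2,
                                     mu = 0, kappa = 1.5)),
                       tpm = matrix(c(0.92, 0.06, 0.02,
                                      0.12, 0.76, 0.12,
                                      0.04, 0.12, 0.84),
                                    3, 3, byrow = TRUE),
                       beta_true = c(SP = 0.3, windDir = -0.4,
                                     "SP:windDir" = -0.2,
                                     "SP:windSp" = 0.15,
                                     "windDir:windSp" = -0.25),
                       storm_params = list(count = 4, drift_speed_kmh = 30,
                                           amplitude_pa = 0.05,
                                           scale_km = 300),
                       wind_params = list(mean_speed = 10,
                                          corr_scale_km = 800),
                       seed = 1) {
  if (any(abs(rowSums(tpm) - 1) > 1e-8)) stop("tpm rows must sum to 1")
  structure(as.list(environment()), class = "sim_config")
}

# fixed covariate-scaling constants used by the generator's choice law so
# the simulated coefficients live on the same scale the fitter uses:
# windDir folded from uniform headings is ~U(0,180) (mean 90, sd 180/sqrt(12));
# windSp is gamma(4, 2.5) (mean 10, sd 5).
GEN_SCALING <- list(windDir_mean = 90, windDir_sd = 180 / sqrt(12),
                    windSp_mean = 10, windSp_sd = 5)

#' Simulate a smooth wind field
#'
#' A uniform westerly of the configured mean speed plus a divergence-free
#' perturbation derived from a small set of random travelling sinusoidal
#' streamfunction modes with wavelengths near the configured correlation
#' scale. Perturbation amplitudes are bounded so speeds stay within
#' `[0, 3 x mean]`.
#'
#' @param cfg a [sim_config()].
#' @param times POSIXct vector of hourly time slices.
#' @param lats,lons grid axes (degrees).
#' @param n_modes number of sinusoidal modes.
#' @return a [wind_field()].
#' @export
simulate_wind_field <- function(cfg, times, lats, lons, n_modes = 6) {
  set.seed(cfg$seed + 101)
  wp <- cfg$wind_params
  nt <- length(times); nla <- length(lats); nlo <- length(lons)
  u <- array(wp$mean_speed, c(nt, nla, nlo))
  v <- array(0, c(nt, nla, nlo))
  if (wp$mean_speed > 0 && n_modes > 0) {
    km_per_deg <- pi * EARTH_RADIUS_KM / 180
    wl_deg <- (wp$corr_scale_km * 2) / km_per_deg  # wavelength ~ 2x corr scale
    amp_cap <- 0.8 * wp$mean_speed / n_modes
    th <- as.numeric(times - times[1]) / 3600
    for (m in seq_len(n_modes)) {
      kx <- 2 * pi / (wl_deg * stats::runif(1, 0.7, 1.4))
      ky <- 2 * pi / (wl_deg * stats::runif(1, 0.7, 1.4))
      ph <- stats::runif(1, 0, 2 * pi)
      om <- stats::runif(1, -0.05, 0.05)   # slow temporal evolution, rad/h
      a <- stats::runif(1, 0.3, 1) * amp_cap
      for (t in seq_len(nt)) {
        arg <- outer(ky * lats, kx * lons, "+") + ph + om * th[t]
        # streamfunction psi = (a/k) sin(arg): u = -dpsi/dlat, v = dpsi/dlon
        u[t, , ] <- u[t, , ] - a * (ky / sqrt(kx^2 + ky^2)) * cos(arg)
        v[t, , ] <- v[t, , ] + a * (kx / sqrt(kx^2 + ky^2)) * cos(arg)
      }
    }
    spd <- sqrt(u^2 + v^2)
    cap <- 3 * wp$mean_speed
    over <- spd > cap
    if (any(over)) {
      u[over] <- u[over] * cap / spd[over]
      v[over] <- v[over] * cap / spd[over]
    }
  }
  wind_field(times, lats, lons, u, v)
}

#' Simulate drifting storm-like microbarom sources
#'
#' Each storm is a compact isotropic source that drifts along a fixed
#' great-circle heading at the configured speed; amplitude is constant over
#' the storm's life.
#'
#' @param cfg a [sim_config()].
#' @param times POSIXct vector of hourly time slices.
#' @param lat_range,lon_range domain in which storm centres are seeded.
#' @return list (one element per time) of data.frames with `lat`, `lon`,
#'   `amplitude` (Pa at the reference distance), `scale_km`.
#' @export
simulate_storm_sources <- function(cfg, times,
                                   lat_range = c(-62, -30),
                                   lon_range = c(25, 80)) {
  set.seed(cfg$seed + 202)
  sp <- cfg$storm_params
  n <- sp$count
  if (n == 0) return(lapply(times, function(t) {
    data.frame(lat = numeric(0), lon = numeric(0), amplitude = numeric(0),
               scale_km = numeric(0))
  }))
  lat0 <- stats::runif(n, lat_range[1], lat_range[2])
  lon0 <- stats::runif(n, lon_range[1], lon_range[2])
  headings <- stats::runif(n, 0, 360)
  amp <- sp$amplitude_pa * exp(stats::rnorm(n, 0, 0.3))
  hours <- as.numeric(times - times[1], units = "hours")
  lapply(hours, function(h) {
    d <- sp$drift_speed_kmh * h
    pos <- destination_point(lat0, lon0, headings, d)
    data.frame(lat = pos$lat, lon = pos$lon, amplitude = amp,
               scale_km = sp$scale_km)
  })
}

# sample a Markov state sequence
simulate_markov_states <- function(tpm, n, init = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(tpm)
  s <- integer(n)
  s[1] <- if (is.null(init)) sample.int(k, 1, prob = stationary_dist(tpm)) else init
  for (t in 2:n) s[t] <- sample.int(k, 1, prob = tpm[s[t - 1], ])
  s
}

# covariates of the six sectors of one decision, on the generator's fixed
# scale; returns list(X = 6 x 5 design, windDir, windSp, SP_z, raw SP)
decision_covariates <- function(lat, lon, ref_bearing, sources, wind,
                                aperture = 60, radius_km = 2000,
                                n_r = 20, n_theta = 24) {
  sectors <- make_sectors(lat, lon, ref_bearing, aperture = aperture,
                          radius_km = radius_km)
  grid <- polar_grid(lat, lon, radius_km = radius_km, n_r = n_r,
                     n_theta = n_theta)
  field <- received_field(sources, lat, lon, grid)
  sp_raw <- sector_sp(field, sectors)
  sp_z <- zstandardize_choice_set(sp_raw)
  wdir <- fold_angle_0_180(sectors$center_bearing, wind$direction_to)
  wd <- (wdir - GEN_SCALING$windDir_mean) / GEN_SCALING$windDir_sd
  ws <- (wind$speed - GEN_SCALING$windSp_mean) / GEN_SCALING$windSp_sd
  X <- cbind(SP = sp_z, windDir = wd, "SP:windDir" = sp_z * wd,
             "SP:windSp" = sp_z * ws, "windDir:windSp" = wd * ws)
  list(X = X, sectors = sectors, SP_raw = sp_raw, SP_z = sp_z,
       windDir = wdir, windSp = wind$speed)
}

softmax_draw <- function(eta) {
  p <- exp(eta - max(eta))
  p <- p / sum(p)
  sample.int(length(eta), 1, prob = p)
}

#' Simulate one bird's track with a known sector-choice law
#'
#' The bird alternates between travel, search and rest according to the
#' configured Markov chain. On each entry into the travel state (a decision
#' event) the circle around the bird is tiled into six sectors referenced to
#' the current heading; sector sound pressure is integrated from the storm
#' sources, wind covariates are evaluated at the bird, and the new heading
#' is the centre of a sector drawn from the conditional-logit law with the
#' configured true coefficients. Within states, headings evolve by von
#' Mises turning angles and gamma step lengths.
#'
#' @param cfg a [sim_config()].
#' @param wind a [wind_field()] covering the domain.
#' @param sources list of hourly source tables from
#'   [simulate_storm_sources()], aligned with `wind$times`.
#' @param bird_id identifier stored in the output.
#' @param start_time POSIXct time of the first fix.
#' @param lat_range latitude band outside which the track is truncated.
#' @return data.frame track: `bird_id`, `time`, `lat`, `lon`, `true_state`
#'   (1 travel / 2 search / 3 rest), `decision_flag`, `chosen_sector`
#'   (sector index 1-6 relative to the pre-decision heading), with the
#'   decision log in attribute `decisions`.
#' @export
simulate_track <- function(cfg, wind, sources, bird_id = "bird1",
                           start_time = wind$times[1],
                           lat_range = c(-68, -22),
                           lon_range = c(12, 98)) {
  n <- cfg$n_days * 24 * 60 / cfg$fixes_interval_min
  dt_h <- cfg$fixes_interval_min / 60
  lat <- cfg$colony_lat; lon <- cfg$colony_lon
  heading <- stats::runif(1, 0, 360)
  state <- 1L   # depart in directed flight
  out <- data.frame(bird_id = bird_id,
                    time = start_time + (seq_len(n) - 1) * dt_h * 3600,
                    lat = NA_real_, lon = NA_real_, true_state = NA_integer_,
                    decision_flag = FALSE, chosen_sector = NA_integer_)
  decisions <- list()
  sp <- cfg$state_params
  for (t in seq_len(n)) {
    prev_state <- state
    if (t > 1) state <- sample.int(3, 1, prob = cfg$tpm[prev_state, ])
    # state at fix t governs the step leaving fix t
    out$lat[t] <- lat; out$lon[t] <- lon; out$true_state[t] <- state
    if (lat < lat_range[1] || lat > lat_range[2] ||
        lon < lon_range[1] || lon > lon_range[2]) {
      warning(sprintf("bird %s left the domain; track truncated at fix %d",
                      bird_id, t))
      out <- out[seq_len(t), , drop = FALSE]
      break
    }
    entered_travel <- state == 1L && (t == 1 || prev_state != 1L)
    if (entered_travel) {
      hi <- which.min(abs(as.numeric(wind$times) - as.numeric(out$time[t])))
      w <- wind_at(wind, lat, lon, out$time[t])
      cov <- decision_covariates(lat, lon, heading, sources[[hi]], w)
      eta <- as.numeric(cov$X %*% cfg$beta_true[colnames(cov$X)])
      j <- softmax_draw(eta)
      heading <- cov$sectors$center_bearing[j]
      out$decision_flag[t] <- TRUE
      out$chosen_sector[t] <- j
      decisions[[length(decisions) + 1]] <-
        list(t = t, time = out$time[t], lat = lat, lon = lon,
             ref_bearing = cov$sectors$center_bearing[1],
             chosen_sector = j, covariates = cov)
    } else {
      pars <- sp[[state]]
      turn <- rvonmises(1, pars$mu, pars$kappa)
      heading <- (heading - rad2deg(turn)) %% 360   # left turn positive
    }
    pars <- sp[[state]]
    step <- stats::rgamma(1, shape = pars$shape, scale = pars$scale)
    pos <- destination_point(lat, lon, heading, step)
    lat <- pos$lat; lon <- pos$lon
  }
  attr(out, "decisions") <- decisions
  attr(out, "seed") <- cfg$seed
  out
}

# von Mises sampler (Best & Fisher 1979 rejection method)
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c_ <- kappa * (r - f)
      if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1))
        break
      }
    }
  }
  ((out + mu + pi) %% (2 * pi)) - pi
}

#' Simulate the full synthetic study
#'
#' Wind, storms and one track per bird under one seed; birds are assigned
#' alternating sexes.
#'
#' @param cfg a [sim_config()].
#' @return list with `cfg`, `wind`, `sources`, `tracks` (list of per-bird
#'   data.frames), `birds` (data.frame with `bird_id`, `sex`).
#' @export
simulate_study <- function(cfg) {
  times <- as.POSIXct("2013-02-01 00:00:00", tz = "UTC") +
    3600 * (0:(cfg$n_days * 24))
  wind <- simulate_wind_field(cfg, times, lats = seq(-70, -20, by = 1),
                              lons = seq(10, 100, by = 1))
  sources <- simulate_storm_sources(cfg, times)
  birds <- data.frame(
    bird_id = sprintf("bird%02d", seq_len(cfg$n_birds)),
    sex = rep(c("F", "M"), length.out = cfg$n_birds)
  )
  tracks <- lapply(seq_len(cfg$n_birds), function(i) {
    set.seed(cfg$seed * 1000 + i)
    simulate_track(cfg, wind, sources, bird_id = birds$bird_id[i],
                   start_time = times[1])
  })
  list(cfg = cfg, wind = wind, sources = sources, tracks = tracks,
       birds = birds)
}

#' Fast choice-set generator with known coefficients
#'
#' Generates matched choice sets directly (without track simulation) for
#' calibration studies: per stratum, six sector sound pressures are drawn
#' lognormally and z-scored, a wind heading is drawn uniformly and folded
#' against the six tiling sector bearings, wind speed is gamma(4, 2.5)
#' (mean 10 m/s), and the chosen sector follows the conditional-logit law
#' with coefficients `beta_true` on the generator-scaled covariates.
#'
#' @param n_birds number of birds (clusters).
#' @param dp_per_bird decision points (strata) per bird.
#' @param beta_true named coefficients as in [sim_config()].
#' @param seed integer seed.
#' @return covariate rows ready for [choice_fit()]: `stratum_id`,
#'   `bird_id`, `sex`, `sector_index`, `chosen`, `SP_z`, `windDir`,
#'   `windSp`.
#' @export
simulate_choice_data <- function(n_birds = 60, dp_per_bird = 30,
                                 beta_true = sim_config()$beta_true,
                                 seed = 1) {
  set.seed(seed)
  n <- n_birds * dp_per_bird
  sexes <- rep(c("F", "M"), length.out = n_birds)
  sp_raw <- matrix(stats::rlnorm(6 * n, meanlog = 0, sdlog = 1), n, 6)
  sp_z <- (sp_raw - rowMeans(sp_raw)) / apply(sp_raw, 1, stats::sd)
  ref <- stats::runif(n, 0, 360)
  centers <- (ref + rep(60 * 0:5, each = n)) %% 360   # n x 6
  dim(centers) <- c(n, 6)
  wind_to <- stats::runif(n, 0, 360)
  wdir <- fold_angle_0_180(centers, wind_to)
  wsp <- stats::rgamma(n, shape = 4, scale = 2.5)
  wd <- (wdir - GEN_SCALING$windDir_mean) / GEN_SCALING$windDir_sd
  ws <- (wsp - GEN_SCALING$windSp_mean) / GEN_SCALING$windSp_sd
  bt <- beta_true[c("SP", "windDir", "SP:windDir", "SP:windSp",
                    "windDir:windSp")]
  eta <- bt[1] * sp_z + bt[2] * wd + bt[3] * sp_z * wd +
    bt[4] * sp_z * ws + bt[5] * wd * ws
  p <- exp(eta - apply(eta, 1, max))
  p <- p / rowSums(p)
  u <- stats::runif(n)
  cum <- t(apply(p, 1, cumsum))
  j <- pmin(rowSums(cum < u) + 1L, 6L)
  out <- data.frame(
    stratum_id = rep(seq_len(n), each = 6),
    bird_id = rep(sprintf("bird%03d", rep(seq_len(n_birds),
                                          each = dp_per_bird)), each = 6),
    sex = rep(rep(sexes, each = dp_per_bird), each = 6),
    sector_index = rep(1:6, n),
    chosen = as.vector(t(matrix(1:6, n, 6, byrow = TRUE) == j)),
    SP_z = as.vector(t(sp_z)),
    windDir = as.vector(t(wdir)),
    windSp = rep(wsp, each = 6)
  )
  attr(out, "beta_true") <- beta_true
  attr(out, "seed") <- seed
  out
}

#' Write simulated tracks to CSV
#' @param tracks list of track data.frames from [simulate_track()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_tracks_csv <- function(tracks, file) {
  df <- do.call(rbind, tracks)
  df$time <- format(df$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
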