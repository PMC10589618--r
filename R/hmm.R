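# Three-state hidden Markov model on step length (gamma) and turning angle
# (von Mises), the standard emission families for movement segmentation.
# Fitting is direct numerical maximisation of the scaled forward likelihood
# with working-scale transforms and random restarts.

MIN_STEP_KM <- 0.001  # steps below 1 m are floored so the gamma density stays finite

#' Compute step lengths and turning angles from a track
#'
#' Steps are great-circle distances to the next fix; turning angles are the
#' signed change of bearing between consecutive steps, wrapped to (-pi, pi],
#' with counterclockwise (left) turns positive. The first fix has no turn.
#' Gaps longer than `gap_factor` times the nominal interval are flagged and
#' later treated as independent likelihood segments.
#'
#' @param track data.frame with columns `lat`, `lon` and optionally `time`
#'   (POSIXct) for gap detection; must be chronologically ordered with
#'   unique timestamps.
#' @param nominal_interval_min nominal fix interval in minutes.
#' @param gap_factor multiple of the nominal interval above which a gap
#'   breaks the series.
#' @return data.frame with `step_km` (NA for the final fix), `turn_rad`
#'   (NA for the first and final fixes and after gaps), `gap_flag`.
#' @export
compute_steps_turns <- function(track, nominal_interval_min = 15,
                                gap_factor = 2) {
  n <- nrow(track)
  stopifnot(n >= 3)
  if (!is.null(track$time)) {
    dt <- diff(as.numeric(track$time))
    if (any(dt == 0)) stop("duplicate timestamps in track")
    if (any(dt < 0)) stop("track not chronologically ordered")
    gap <- c(dt / 60 > gap_factor * nominal_interval_min, FALSE)
  } else {
    gap <- rep(FALSE, n)
  }
  step <- c(great_circle_km(track$lat[-n], track$lon[-n],
                            track$lat[-1], track$lon[-1]), NA)
  step[!is.na(step) & step < MIN_STEP_KM] <- MIN_STEP_KM
  bearing <- rep(NA_real_, n)
  for (i in seq_len(n - 1)) {
    if (track$lat[i] != track$lat[i + 1] || track$lon[i] != track$lon[i + 1]) {
      bearing[i] <- initial_bearing(track$lat[i], track$lon[i],
                                    track$lat[i + 1], track$lon[i + 1])
    }
  }
  turn <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    if (!is.na(bearing[i - 1]) && !is.na(bearing[i]) && !gap[i - 1]) {
      # left turn positive: bearing decreases clockwise-from-north
      turn[i] <- deg2rad(signed_angle_diff(bearing[i], bearing[i - 1]))
      if (turn[i] <= -pi) turn[i] <- turn[i] + 2 * pi
    }
  }
  data.frame(step_km = step, turn_rad = turn, gap_flag = gap)
}

# von Mises density; besselI with expon.scaled guards large kappa.
dvonmises <- function(x, mu, kappa) {
  exp(kappa * (cos(x - mu) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Construct an HMM parameter set
#'
#' @param step_shape,step_scale per-state gamma parameters for step length (km).
#' @param turn_mean,turn_kappa per-state von Mises parameters for turning
#'   angle (radians).
#' @param tpm transition probability matrix (rows sum to 1).
#' @param delta initial state distribution; default the stationary
#'   distribution of `tpm`.
#' @return object of class `hmm_params`.
#' @export
hmm_params <- function(step_shape, step_scale, turn_mean, turn_kappa,
                       tpm, delta = NULL) {
  k <- length(step_shape)
  stopifnot(length(step_scale) == k, length(turn_mean) == k,
            length(turn_kappa) == k, nrow(tpm) == k, ncol(tpm) == k)
  if (any(abs(rowSums(tpm) - 1) > 1e-8)) stop("tpm rows must sum to 1")
  if (is.null(delta)) delta <- stationary_dist(tpm)
  structure(list(step_shape = step_shape, step_scale = step_scale,
                 turn_mean = turn_mean, turn_kappa = turn_kappa,
                 tpm = tpm, delta = delta, n_states = k),
            class = "hmm_params")
}

stationary_dist <- function(tpm) {
  k <- nrow(tpm)
  A <- rbind(t(diag(k) - tpm), rep(1, k))
  b <- c(rep(0, k), 1)
  as.numeric(qr.solve(A, b))
}

# n x k matrix of per-observation emission densities. Missing turns
# contribute only the step density (density 1 for the turn component).
emission_densities <- function(params, step, turn) {
  k <- params$n_states
  n <- length(step)
  dens <- matrix(1, n, k)
  for (j in seq_len(k)) {
    ok <- !is.na(step)
    dens[ok, j] <- stats::dgamma(step[ok], shape = params$step_shape[j],
                                 scale = params$step_scale[j])
    okt <- !is.na(turn)
    dens[okt, j] <- dens[okt, j] *
      dvonmises(turn[okt], params$turn_mean[j], params$turn_kappa[j])
  }
  if (any(!is.finite(dens))) {
    bad <- which(!is.finite(rowSums(dens)))[1]
    stop(sprintf("non-finite emission density at observation %d", bad))
  }
  dens
}

#' HMM log-likelihood by the scaled forward algorithm
#'
#' @param params an [hmm_params()] object.
#' @param series data.frame from [compute_steps_turns()] (columns `step_km`,
#'   `turn_rad`, optional `gap_flag`); rows with missing steps (series ends)
#'   are dropped. Gap flags split the series into independent segments that
#'   each restart from the initial distribution.
#' @return log-likelihood (scalar).
#' @export
hmm_loglik <- function(params, series) {
  use <- !is.na(series$step_km)
  step <- series$step_km[use]
  turn <- series$turn_rad[use]
  gap <- if (!is.null(series$gap_flag)) series$gap_flag[use] else
    rep(FALSE, length(step))
  dens <- emission_densities(params, step, turn)
  n <- length(step)
  ll <- 0
  phi <- params$delta * dens[1, ]
  s <- sum(phi)
  ll <- log(s); phi <- phi / s
  if (n >= 2) {
    for (t in 2:n) {
      if (gap[t - 1]) {
        phi <- params$delta * dens[t, ]
      } else {
        phi <- as.numeric(phi %*% params$tpm) * dens[t, ]
      }
      s <- sum(phi)
      if (!is.finite(s) || s <= 0) {
        stop(sprintf("degenerate forward probability at observation %d", t))
      }
      ll <- ll + log(s)
      phi <- phi / s
    }
  }
  ll
}

# --- working-scale transforms for unconstrained optimisation ----------------

hmm_pack <- function(params) {
  k <- params$n_states
  tpm_work <- numeric(0)
  for (i in seq_len(k)) {
    ref <- params$tpm[i, i]
    tpm_work <- c(tpm_work, log(params$tpm[i, -i] / ref))
  }
  c(log(params$step_shape), log(params$step_scale),
    tan(params$turn_mean / 2), log(params$turn_kappa), tpm_work)
}

hmm_unpack <- function(w, k) {
  sh <- exp(w[1:k]); sc <- exp(w[(k + 1):(2 * k)])
  mu <- 2 * atan(w[(2 * k + 1):(3 * k)])
  ka <- exp(w[(3 * k + 1):(4 * k)])
  tw <- w[-(1:(4 * k))]
  tpm <- matrix(0, k, k)
  idx <- 1
  for (i in seq_len(k)) {
    e <- exp(tw[idx:(idx + k - 2)]); idx <- idx + k - 1
    row <- numeric(k); row[i] <- 1; row[-i] <- e
    tpm[i, ] <- row / sum(row)
  }
  hmm_params(sh, sc, mu, ka, tpm)
}

#' Fit the HMM by direct likelihood maximisation
#'
#' Maximises [hmm_loglik()] over working-scale parameters (log step shape and
#' scale, log turn concentration, half-angle tangent for the turn mean,
#' multinomial-logit rows of the transition matrix) with `optim(method =
#' "BFGS")`, restarting from `n_restarts` perturbations of `init`. The
#' initial state distribution is tied to the stationary distribution of the
#' transition matrix.
#'
#' @param series data.frame from [compute_steps_turns()].
#' @param init an [hmm_params()] starting point.
#' @param n_restarts number of random restarts (the first uses `init`
#'   unperturbed).
#' @param seed integer seed controlling restart perturbations.
#' @param jitter_sd working-scale s.d. of restart perturbations.
#' @return the best `hmm_params`, with attributes `loglik`, `convergence`
#'   (per-restart optim codes) and `restart_logliks`.
#' @export
fit_hmm <- function(series, init, n_restarts = 5, seed = 1, jitter_sd = 0.3) {
  w0 <- hmm_pack(init)
  k <- init$n_states
  negll <- function(w) {
    p <- tryCatch(hmm_unpack(w, k), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    # extreme working values probed by the optimiser can NaN the densities
    v <- suppressWarnings(
      tryCatch(-hmm_loglik(p, series), error = function(e) 1e10))
    if (!is.finite(v)) 1e10 else v
  }
  rng <- local({ set.seed(seed); lapply(seq_len(n_restarts), function(i) {
    if (i == 1) rep(0, length(w0)) else stats::rnorm(length(w0), 0, jitter_sd)
  }) })
  fits <- lapply(rng, function(eps) {
    tryCatch(stats::optim(w0 + eps, negll, method = "BFGS",
                          control = list(maxit = 300, reltol = 1e-10)),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("all HMM restarts failed to optimise")
  lls <- vapply(fits, function(f) -f$value, numeric(1))
  best <- fits[[which.max(lls)]]
  out <- hmm_unpack(best$par, k)
  base_ll <- -negll(w0)
  if (max(lls) < base_ll - 1e-6) {  # never return worse than the start
    out <- hmm_unpack(w0, k)
    attr(out, "loglik") <- base_ll
  } else {
    attr(out, "loglik") <- max(lls)
  }
  attr(out, "restart_logliks") <- lls
  attr(out, "convergence") <- vapply(fits, `[[`, numeric(1), "convergence")
  out
}

#' Most probable state path (Viterbi decoding)
#'
#' Ties are broken toward the lower state index. Gap-flagged positions
#' restart the recursion from the initial distribution.
#'
#' @inheritParams hmm_loglik
#' @return integer state sequence, one entry per used observation.
#' @export
viterbi_decode <- function(params, series) {
  use <- !is.na(series$step_km)
  step <- series$step_km[use]
  turn <- series$turn_rad[use]
  gap <- if (!is.null(series$gap_flag)) series$gap_flag[use] else
    rep(FALSE, length(step))
  ldens <- log(emission_densities(params, step, turn))
  n <- length(step); k <- params$n_states
  ltpm <- log(params$tpm); ldelta <- log(params$delta)
  v <- matrix(-Inf, n, k)
  bp <- matrix(0L, n, k)
  v[1, ] <- ldelta + ldens[1, ]
  if (n >= 2) {
    for (t in 2:n) {
      if (gap[t - 1]) {
        v[t, ] <- ldelta + ldens[t, ]
      } else {
        for (j in seq_len(k)) {
          cand <- v[t - 1, ] + ltpm[, j]
          bp[t, j] <- which.max(cand)  # which.max takes the lowest index on ties
          v[t, j] <- cand[bp[t, j]] + ldens[t, j]
        }
      }
    }
  }
  path <- integer(n)
  path[n] <- which.max(v[n, ])
  if (n >= 2) {
    for (t in (n - 1):1) {
      path[t] <- if (gap[t]) which.max(v[t, ]) else bp[t + 1, path[t + 1]]
    }
  }
  path
}

#' Map fitted states to behaviours by mean step length
#'
#' States are ranked by gamma mean step (shape x scale): the fastest is
#' labelled `travel`, the middle `search`, the slowest `rest`. The turn
#' concentration of each state is attached for a manual sanity check (travel
#' should be the most concentrated).
#'
#' @param params fitted 3-state [hmm_params()].
#' @return named character vector mapping state index to behaviour, with a
#'   `turn_kappa` attribute.
#' @export
label_states <- function(params) {
  stopifnot(params$n_states == 3)
  m <- params$step_shape * params$step_scale
  if (anyDuplicated(m)) stop("tied mean step lengths; map states manually")
  lab <- character(3)
  lab[order(m)] <- c("rest", "search", "travel")
  names(lab) <- paste0("state", 1:3)
  attr(lab, "mean_step_km") <- m
  attr(lab, "turn_kappa") <- params$turn_kappa
  lab
}

#' Agreement between decoded and reference behaviour labels
#'
#' @param decoded,reference equal-length vectors of behaviour labels.
#' @return list with `overall_pct` and `per_class_pct` (agreement among
#'   fixes whose reference label is that class).
#' @export
classification_accuracy <- function(decoded, reference) {
  stopifnot(length(decoded) == length(reference))
  if (!all(unique(decoded) %in% unique(reference))) {
    stop("decoded labels contain classes absent from the reference")
  }
  overall <- 100 * mean(decoded == reference)
  cls <- sort(unique(reference))
  per <- vapply(cls, function(c) {
    100 * mean(decoded[reference == c] == c)
  }, numeric(1))
  names(per) <- cls
  list(overall_pct = overall, per_class_pct = per)
}
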