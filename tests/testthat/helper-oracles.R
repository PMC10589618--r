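# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: distances by the spherical law of cosines,
# HMM likelihoods by exhaustive path enumeration, conditional-logit MLEs by
# grid search.

R_EARTH <- 6371.0088

# spherical law of cosines distance (km)
sloc_km <- function(lat1, lon1, lat2, lon2) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  c <- sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl)
  R_EARTH * acos(pmin(pmax(c, -1), 1))
}

# forward azimuth, coded independently of the package
azimuth_deg <- function(lat1, lon1, lat2, lon2) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  th <- atan2(sin(dl) * cos(p2),
              cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl))
  (th * 180 / pi) %% 360
}

# local emission density (gamma step x von Mises turn); NA turn contributes 1
obs_dens <- function(step, turn, shape, scale, mu, kappa) {
  d <- dgamma(step, shape = shape, scale = scale)
  if (!is.na(turn)) {
    d <- d * exp(kappa * cos(turn - mu)) / (2 * pi * besselI(kappa, 0))
  }
  d
}

# exhaustive-path HMM likelihood and best path for short series
hmm_bruteforce <- function(params, step, turn) {
  n <- length(step); k <- params$n_states
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  dens <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    for (t in seq_len(n)) {
      dens[t, j] <- obs_dens(step[t], turn[t], params$step_shape[j],
                             params$step_scale[j], params$turn_mean[j],
                             params$turn_kappa[j])
    }
  }
  probs <- apply(paths, 1, function(s) {
    p <- params$delta[s[1]] * dens[1, s[1]]
    if (n >= 2) {
      for (t in 2:n) p <- p * params$tpm[s[t - 1], s[t]] * dens[t, s[t]]
    }
    p
  })
  list(loglik = log(sum(probs)),
       best_path = paths[which.max(probs), ],
       best_prob = max(probs))
}

# random small HMM parameter set
random_hmm <- function(k) {
  tpm <- matrix(runif(k * k, 0.2, 1), k, k)
  tpm <- tpm / rowSums(tpm)
  hmm_params(step_shape = runif(k, 0.8, 6), step_scale = runif(k, 0.3, 4),
             turn_mean = runif(k, -1, 1), turn_kappa = runif(k, 0.2, 6),
             tpm = tpm)
}

# conditional-logit MLE by two-stage grid search (coarse 0.01, fine 0.001)
grid_mle <- function(X, stratum, chosen, lo = -1.5, hi = 1.5) {
  stopifnot(ncol(X) == 2)
  ll_grid <- function(B) {
    eta <- X %*% t(B)
    S <- rowsum(exp(eta), stratum)
    colSums(eta[chosen, , drop = FALSE]) - colSums(log(S))
  }
  g1 <- seq(lo, hi, by = 0.01)
  B <- as.matrix(expand.grid(g1, g1))
  best <- B[which.max(ll_grid(B)), ]
  g2a <- seq(best[1] - 0.02, best[1] + 0.02, by = 0.001)
  g2b <- seq(best[2] - 0.02, best[2] + 0.02, by = 0.001)
  B2 <- as.matrix(expand.grid(g2a, g2b))
  B2[which.max(ll_grid(B2)), ]
}

# small matched choice data with weak known effects, 2 covariates
toy_choice_rows <- function(n_strata = 8, n_birds = 4, beta = c(0.4, -0.3),
                            seed = 42) {
  set.seed(seed)
  rows <- lapply(seq_len(n_strata), function(s) {
    x1 <- rnorm(6); x2 <- rnorm(6)
    eta <- beta[1] * x1 + beta[2] * x2
    p <- exp(eta) / sum(exp(eta))
    j <- sample.int(6, 1, prob = p)
    data.frame(stratum_id = s,
               bird_id = sprintf("b%d", 1 + (s - 1) %% n_birds),
               chosen = seq_len(6) == j, x1 = x1, x2 = x2)
  })
  do.call(rbind, rows)
}

# a simple regular track along a meridian (northward), fixed step km
meridian_track <- function(n, step_km, lat0 = -46, lon0 = 52,
                           interval_min = 15) {
  lat <- lat0 + (seq_len(n) - 1) * step_km / (pi * R_EARTH / 180)
  data.frame(lat = lat, lon = lon0,
             time = as.POSIXct("2013-02-01", tz = "UTC") +
               (seq_len(n) - 1) * interval_min * 60)
}
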