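hourly <- function(n) as.POSIXct("2013-02-01", tz = "UTC") + 3600 * (0:(n - 1))

test_that("simulated wind fields honour the configured regime", {
  cfg0 <- sim_config(wind_params = list(mean_speed = 0, corr_scale_km = 500))
  calm <- simulate_wind_field(cfg0, hourly(3), seq(-50, -40), seq(45, 55))
  expect_true(all(calm$u == 0) && all(calm$v == 0))
  cfgc <- sim_config(wind_params = list(mean_speed = 8, corr_scale_km = 500))
  const <- simulate_wind_field(cfgc, hourly(3), seq(-50, -40), seq(45, 55),
                               n_modes = 0)
  expect_true(all(const$u == 8) && all(const$v == 0))
  cfg <- sim_config(seed = 5)
  wf <- simulate_wind_field(cfg, hourly(5), seq(-60, -30, by = 0.5),
                            seq(30, 80, by = 0.5))
  spd <- sqrt(wf$u^2 + wf$v^2)
  expect_true(all(spd >= 0 & spd <= 3 * cfg$wind_params$mean_speed + 1e-9))
  # spatial autocorrelation decays with lag along longitude
  u1 <- wf$u[1, 30, ]
  lag_cor <- function(l) cor(u1[seq_len(length(u1) - l)], u1[-seq_len(l)])
  expect_gt(lag_cor(2), lag_cor(40))
})

test_that("storm sources drift at the configured speed", {
  cfg0 <- sim_config(storm_params = list(count = 0, drift_speed_kmh = 30,
                                         amplitude_pa = 0.05,
                                         scale_km = 300))
  silent <- simulate_storm_sources(cfg0, hourly(3))
  expect_true(all(vapply(silent, nrow, numeric(1)) == 0))
  cfg_still <- sim_config(storm_params = list(count = 1, drift_speed_kmh = 0,
                                              amplitude_pa = 0.05,
                                              scale_km = 300))
  still <- simulate_storm_sources(cfg_still, hourly(4))
  for (h in 2:4) expect_equal(still[[h]], still[[1]])
  cfg_mv <- sim_config(storm_params = list(count = 3, drift_speed_kmh = 40,
                                           amplitude_pa = 0.05,
                                           scale_km = 300))
  mv <- simulate_storm_sources(cfg_mv, hourly(5))
  expect_true(all(mv[[1]]$amplitude > 0))
  for (h in 2:5) {
    disp <- great_circle_km(mv[[h - 1]]$lat, mv[[h - 1]]$lon,
                            mv[[h]]$lat, mv[[h]]$lon)
    expect_equal(disp, rep(40, 3), tolerance = 1e-6)
  }
})

test_that("state dwell times follow the geometric law of the chain", {
  cfg <- sim_config()
  st <- infrachoice:::simulate_markov_states(cfg$tpm, 60000, seed = 50)
  r <- rle(st)
  for (s in 1:3) {
    dw <- r$lengths[r$values == s]
    dw <- dw[-c(1, length(dw))]           # censored first/last runs
    p_stay <- cfg$tpm[s, s]
    # chi-square GOF against the geometric dwell-time law
    kmax <- max(5, floor(quantile(dw, 0.98)))
    obs <- tabulate(pmin(dw, kmax), nbins = kmax)
    pr <- (1 - p_stay) * p_stay^(0:(kmax - 1))
    pr[kmax] <- p_stay^(kmax - 1)          # tail lumped into the last bin
    keep <- pr * length(dw) >= 5
    stat <- sum((obs[keep] - length(dw) * pr[keep])^2 /
                  (length(dw) * pr[keep]))
    pval <- pchisq(stat, df = sum(keep) - 1, lower.tail = FALSE)
    expect_gt(pval, 0.01)
  }
})

test_that("sector choices follow the conditional-logit law", {
  # null coefficients: uniform 1/6 frequencies within binomial error
  beta0 <- c(SP = 0, windDir = 0, "SP:windDir" = 0, "SP:windSp" = 0,
             "windDir:windSp" = 0)
  rows0 <- simulate_choice_data(n_birds = 100, dp_per_bird = 30,
                                beta_true = beta0, seed = 51)
  counts <- table(rows0$sector_index[rows0$chosen])
  n <- sum(counts)
  expect_equal(length(counts), 6)
  se <- sqrt(n * (1 / 6) * (5 / 6))
  expect_true(all(abs(counts - n / 6) < 4 * se))
  chi <- chisq.test(counts, p = rep(1 / 6, 6))
  expect_gt(chi$p.value, 0.001)
  # overwhelming SP preference: max-SP sector chosen > 90% of the time
  beta_sp <- c(SP = 6, windDir = 0, "SP:windDir" = 0, "SP:windSp" = 0,
               "windDir:windSp" = 0)
  rows_sp <- simulate_choice_data(n_birds = 20, dp_per_bird = 25,
                                  beta_true = beta_sp, seed = 52)
  hit <- tapply(seq_len(nrow(rows_sp)), rows_sp$stratum_id, function(i) {
    sub <- rows_sp[i, ]
    sub$sector_index[sub$chosen] == sub$sector_index[which.max(sub$SP_z)]
  })
  expect_gt(mean(unlist(hit)), 0.9)
})

test_that("empirical choice frequencies match the softmax probabilities", {
  bt <- sim_config()$beta_true
  rows <- simulate_choice_data(n_birds = 50, dp_per_bird = 20,
                               beta_true = bt, seed = 53)
  # expected per-sector counts from the generator's own probability law
  sc <- infrachoice:::GEN_SCALING
  wd <- (rows$windDir - sc$windDir_mean) / sc$windDir_sd
  ws <- (rows$windSp - sc$windSp_mean) / sc$windSp_sd
  eta <- bt["SP"] * rows$SP_z + bt["windDir"] * wd +
    bt["SP:windDir"] * rows$SP_z * wd + bt["SP:windSp"] * rows$SP_z * ws +
    bt["windDir:windSp"] * wd * ws
  p <- unlist(tapply(eta, rows$stratum_id, function(e) {
    exp(e - max(e)) / sum(exp(e - max(e)))
  })[as.character(unique(rows$stratum_id))])
  O <- tapply(rows$chosen, rows$sector_index, sum)
  E <- tapply(p, rows$sector_index, sum)
  stat <- sum((O - E)^2 / E)
  expect_gt(pchisq(stat, df = 5, lower.tail = FALSE), 0.01)
})

test_that("track simulation is reproducible and carries its ground truth", {
  cfg <- sim_config(n_birds = 2, n_days = 2, seed = 9)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$tracks, s2$tracks)
  tr <- s1$tracks[[1]]
  expect_true(all(tr$true_state %in% 1:3))
  expect_true(all(tr$decision_flag == !is.na(tr$chosen_sector)))
  # decisions coincide with entries into the travel state
  ent <- which(tr$true_state == 1 & c(TRUE, tr$true_state[-nrow(tr)] != 1))
  expect_setequal(which(tr$decision_flag), ent)
  # travel-state turning angles are shallow: central 90% interval within
  # roughly (-0.56, 0.56) radians as configured
  pooled <- do.call(rbind, lapply(s1$tracks, function(t) {
    s <- compute_steps_turns(t)
    # within-travel turns only: both adjacent steps in the travel state and
    # no decision jump at this fix
    s$within_travel <- t$true_state == 1 &
      c(NA, t$true_state[-nrow(t)]) == 1 & !t$decision_flag
    s
  }))
  tt <- pooled$turn_rad[pooled$within_travel %in% TRUE &
                          !is.na(pooled$turn_rad)]
  q <- quantile(tt, c(0.05, 0.95))
  expect_gt(q[1], -0.56 - 0.15)
  expect_lt(q[2], 0.58 + 0.15)
})

test_that("end-to-end parameter recovery covers the truth in nearly all replicates", {
  bt <- sim_config()$beta_true
  hits <- matrix(NA, 100, 5)
  for (i in 1:100) {
    rows <- simulate_choice_data(n_birds = 60, dp_per_bird = 30,
                                 beta_true = bt, seed = 500 + i)
    f <- choice_fit(rows, "wind_sp")
    se <- sqrt(diag(f$vcov_robust))
    hits[i, ] <- abs(coef(f) - bt[names(coef(f))]) <= 3 * se
  }
  # +-3 robust SE covers each coefficient in at least 95 of 100 replicates
  expect_true(all(colSums(hits) >= 95))
})
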