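test_that("model specifications produce the documented design columns", {
  rows <- simulate_choice_data(n_birds = 5, dp_per_bird = 4, seed = 60)
  d_wind <- build_design(rows, "wind")
  expect_equal(colnames(d_wind$X), c("windDir", "windDir:windSp"))
  d_full <- build_design(rows, "wind_sp")
  expect_equal(colnames(d_full$X),
               c("SP", "windDir", "SP:windDir", "SP:windSp",
                 "windDir:windSp"))
  expect_error(choice_terms(c("windSp", "windDir")), "constant within strata")
  # scaled columns are centred with unit sd; interactions formed after scaling
  expect_equal(mean(d_full$X[, "windDir"]), 0, tolerance = 1e-12)
  expect_equal(sd(d_full$X[, "windDir"]), 1, tolerance = 1e-12)
  expect_equal(d_full$X[, "SP:windDir"],
               d_full$X[, "SP"] * d_full$X[, "windDir"])
  # strata with missing covariates are dropped whole
  rows2 <- rows
  rows2$windDir[7] <- NA
  expect_message(d2 <- build_design(rows2, "wind"), "dropping 1 strata")
  expect_equal(length(unique(d2$rows$stratum_id)), 19)
})

test_that("conditional-logit likelihood matches closed forms", {
  # beta = 0: -n log 6
  rows <- simulate_choice_data(n_birds = 2, dp_per_bird = 5, seed = 61)
  d <- build_design(rows, "wind_sp")
  st <- infrachoice:::stratum_index(d$rows$stratum_id)
  ch <- as.logical(d$rows$chosen)
  expect_equal(cond_logit_loglik(rep(0, 5), d$X, st, ch), -10 * log(6),
               tolerance = 1e-12)
  # single stratum, indicator covariate, beta = 1: 1 - log(e + 5)
  X1 <- matrix(c(1, 0, 0, 0, 0, 0), ncol = 1)
  ll <- cond_logit_loglik(1, X1, rep(1, 6), c(TRUE, rep(FALSE, 5)))
  expect_equal(ll, 1 - log(exp(1) + 5), tolerance = 1e-12)
  expect_equal(ll, -1.0436, tolerance = 1e-4)
  # a stratum without a chosen row is an error
  expect_error(cond_logit_loglik(1, X1, rep(1, 6), rep(FALSE, 6)),
               "exactly one chosen")
})

test_that("likelihood is invariant to stratum-constant covariate shifts", {
  set.seed(62)
  rows <- toy_choice_rows(n_strata = 12)
  X <- as.matrix(rows[, c("x1", "x2")])
  st <- rows$stratum_id
  ch <- rows$chosen
  beta <- c(0.7, -1.1)
  base <- cond_logit_loglik(beta, X, st, ch)
  for (i in 1:10) {
    offs <- rnorm(12, sd = 5)[st]
    X2 <- X
    X2[, 1] <- X2[, 1] + offs
    expect_equal(cond_logit_loglik(beta, X2, st, ch), base,
                 tolerance = 1e-10)
  }
})

test_that("the Newton MLE matches a brute-force grid search", {
  rows <- toy_choice_rows(n_strata = 8, seed = 63)
  X <- as.matrix(rows[, c("x1", "x2")])
  st <- rows$stratum_id; ch <- rows$chosen
  oracle <- grid_mle(X, st, ch)
  # fit through the package's Newton path on the same design
  rows_fit <- data.frame(stratum_id = rows$stratum_id,
                         bird_id = rows$bird_id, chosen = rows$chosen,
                         SP_z = rows$x1, windDir = rows$x2, windSp = 1)
  # use raw covariates: disable scaling by passing identity constants
  fit <- choice_fit(rows_fit, c("SP", "windDir"),
                    scaling = list(windDir_mean = 0, windDir_sd = 1,
                                   windSp_mean = 0, windSp_sd = 1))
  expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-2)
})

test_that("score vanishes and information is positive definite at the MLE", {
  rows <- simulate_choice_data(n_birds = 20, dp_per_bird = 15, seed = 64)
  fit <- choice_fit(rows, "wind_sp")
  d <- build_design(rows, "wind_sp")
  st <- infrachoice:::stratum_index(d$rows$stratum_id)
  ch <- as.logical(d$rows$chosen)
  parts <- infrachoice:::cond_logit_parts(coef(fit), d$X, st, ch)
  expect_lt(sqrt(sum(parts$grad^2)), 1e-6)
  expect_true(all(eigen(parts$info, symmetric = TRUE)$values > 0))
  expect_true(isSymmetric(fit$vcov_robust, tol = 1e-10))
})

test_that("duplicating every stratum preserves the MLE and halves naive variance", {
  rows <- simulate_choice_data(n_birds = 10, dp_per_bird = 8, seed = 65)
  fit1 <- choice_fit(rows, "wind_sp")
  rows2 <- rows
  rows2$stratum_id <- rows2$stratum_id + max(rows$stratum_id)
  both <- rbind(rows, rows2)
  # hold the scaling constants fixed so the designs are strictly duplicated
  fit2 <- choice_fit(both, "wind_sp", scaling = fit1$scaling)
  expect_equal(coef(fit2), coef(fit1), tolerance = 1e-6)
  expect_equal(diag(fit2$vcov_naive), diag(fit1$vcov_naive) / 2,
               tolerance = 1e-6)
})

test_that("estimates and robust errors agree with survival::clogit", {
  skip_if_not_installed("survival")
  suppressPackageStartupMessages(library(survival))
  rows <- simulate_choice_data(n_birds = 25, dp_per_bird = 12, seed = 66)
  fit <- choice_fit(rows, "wind_sp")
  d <- build_design(rows, "wind_sp")
  df <- as.data.frame(d$X)
  names(df) <- c("sp", "wd", "spwd", "spws", "wdws")
  df$chosen <- as.numeric(d$rows$chosen)
  df$stratum <- d$rows$stratum_id
  df$bird <- d$rows$bird_id
  # one case per stratum: no tied events, so Breslow equals the exact
  # conditional likelihood and supports cluster-robust dfbeta residuals
  cl <- survival::clogit(
    chosen ~ sp + wd + spwd + spws + wdws +
      survival::strata(stratum) + survival::cluster(bird),
    data = df, method = "breslow")
  expect_equal(unname(coef(fit)), unname(coef(cl)), tolerance = 1e-5)
  expect_equal(unname(sqrt(diag(fit$vcov_robust))),
               unname(sqrt(diag(stats::vcov(cl)))), tolerance = 1e-3)
  expect_equal(fit$loglik, unname(cl$loglik[2]), tolerance = 1e-6)
  # one stratum per bird: every bird its own cluster, sandwich equals the
  # independent implementation's robust variance on a 10-stratum instance
  rows1 <- simulate_choice_data(n_birds = 10, dp_per_bird = 1, seed = 67)
  f1 <- choice_fit(rows1, c("SP", "windDir"))
  d1 <- build_design(rows1, c("SP", "windDir"))
  df1 <- data.frame(sp = d1$X[, 1], wd = d1$X[, 2],
                    chosen = as.numeric(d1$rows$chosen),
                    stratum = d1$rows$stratum_id, bird = d1$rows$bird_id)
  cl1 <- survival::clogit(chosen ~ sp + wd + survival::strata(stratum) +
                            survival::cluster(bird), data = df1,
                          method = "breslow")
  expect_equal(unname(sqrt(diag(f1$vcov_robust))),
               unname(sqrt(diag(stats::vcov(cl1)))), tolerance = 1e-3)
})

test_that("QIC weights follow the Akaike-weight formula", {
  expect_equal(qic_weights(c(100, 100)), c(0.5, 0.5))
  w <- qic_weights(c(0, 2, 4))
  expect_equal(w, c(0.6652, 0.2447, 0.0900), tolerance = 1e-3)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  set.seed(68)
  for (i in 1:5) {
    expect_equal(sum(qic_weights(runif(4, 1000, 1100))), 1,
                 tolerance = 1e-12)
  }
})

test_that("QIC reduces to AIC-like penalty under independence", {
  # with every stratum its own cluster and one stratum per bird, the
  # sandwich is close to the naive covariance and the penalty near 2K
  rows <- simulate_choice_data(n_birds = 400, dp_per_bird = 1, seed = 69)
  fit <- choice_fit(rows, "wind_sp")
  pen <- fit$qic - (-2 * fit$loglik)
  expect_equal(pen, 2 * 5, tolerance = 0.2 * 2 * 5)
})

test_that("comparison tables require matching strata", {
  rows <- simulate_choice_data(n_birds = 10, dp_per_bird = 6, seed = 70)
  f1 <- choice_fit(rows, "wind_sp")
  f2 <- choice_fit(rows[rows$stratum_id <= 30, ], "wind")
  expect_error(qic_table(list(a = f1, b = f2)), "different strata")
})

test_that("likelihood-ratio statistic is twice the log-likelihood gain", {
  rows <- simulate_choice_data(n_birds = 30, dp_per_bird = 20, seed = 71)
  fit <- choice_fit(rows, "wind_sp")
  expect_equal(fit$loglik_null, -600 * log(6), tolerance = 1e-10)
  expect_equal(fit$lrt$statistic, 2 * (fit$loglik - fit$loglik_null),
               tolerance = 1e-10)
  # the statistic grows with sample size under a real effect
  rows_s <- simulate_choice_data(n_birds = 25, dp_per_bird = 20, seed = 72)
  rows_l <- simulate_choice_data(n_birds = 100, dp_per_bird = 20, seed = 72)
  expect_gt(choice_fit(rows_l, "wind_sp")$lrt$statistic,
            choice_fit(rows_s, "wind_sp")$lrt$statistic)
})

test_that("concordance counts within-stratum pairs with half ties", {
  # beta = 0: all linear predictors tie, C = 1/2
  expect_equal(concordance_index(rep(0, 12), rep(1:2, each = 6),
                                 c(TRUE, rep(FALSE, 5), TRUE,
                                   rep(FALSE, 5))), 0.5)
  # chosen always strictly largest: C = 1
  eta <- c(5, 1, 2, 3, 4, 0, 9, 1, 1, 1, 1, 1)
  ch <- c(TRUE, rep(FALSE, 5), TRUE, rep(FALSE, 5))
  expect_equal(concordance_index(eta, rep(1:2, each = 6), ch), 1)
  # hand-built 3-stratum example, 15 pairs enumerated by hand:
  # s1: chosen 2 beats (1,0,-1,3,5) -> 3 wins of 5
  # s2: chosen 0 beats (0,0,1,2,-2) -> 1 win + 2 ties of 5
  # s3: chosen 7 beats (1,2,3,4,5) -> 5 wins of 5
  eta3 <- c(2, 1, 0, -1, 3, 5,  0, 0, 0, 1, 2, -2,  7, 1, 2, 3, 4, 5)
  ch3 <- rep(c(TRUE, rep(FALSE, 5)), 3)
  expect_equal(concordance_index(eta3, rep(1:3, each = 6), ch3),
               (3 + 1 + 0.5 * 2 + 5) / 15)
})

test_that("sex-stratified runs recover shared and distinct effects", {
  bt <- sim_config()$beta_true
  rows <- simulate_choice_data(n_birds = 60, dp_per_bird = 25, seed = 73)
  tabs <- sex_stratified_run(rows)
  expect_setequal(names(tabs), c("F", "M"))
  expect_equal(names(tabs$F), c("model", "variables", "K", "QIC", "QICw",
                                "X2", "C"))
  for (s in c("F", "M")) {
    fit <- attr(tabs[[s]], "fits")$wind_sp
    se <- sqrt(diag(fit$vcov_robust))
    expect_true(all(abs(coef(fit) - bt[names(coef(fit))]) < 3 * se))
  }
  # sex-specific truth: females with weak SP response, males strong
  btF <- bt; btF["SP"] <- 0
  btM <- bt; btM["SP"] <- 0.6
  rF <- simulate_choice_data(n_birds = 30, dp_per_bird = 25,
                             beta_true = btF, seed = 74)
  rM <- simulate_choice_data(n_birds = 30, dp_per_bird = 25,
                             beta_true = btM, seed = 75)
  rF <- rF[rF$sex == "F", ]
  rM <- rM[rM$sex == "M", ]
  rM$stratum_id <- rM$stratum_id + max(rF$stratum_id)
  tabs2 <- sex_stratified_run(rbind(rF, rM))
  fF <- attr(tabs2$F, "fits")$wind_sp
  fM <- attr(tabs2$M, "fits")$wind_sp
  dd <- coef(fM)["SP"] - coef(fF)["SP"]
  sed <- sqrt(fM$vcov_robust["SP", "SP"] + fF$vcov_robust["SP", "SP"])
  expect_true(abs(dd - 0.6) < 3 * sed)
})

test_that("separation is reported rather than silently diverging", {
  # a covariate that perfectly identifies the chosen sector
  n <- 30
  rows <- data.frame(stratum_id = rep(1:n, each = 6),
                     bird_id = rep(sprintf("b%d", 1:5), each = 36),
                     chosen = rep(c(TRUE, rep(FALSE, 5)), n),
                     SP_z = rep(c(2, rep(-0.4, 5)), n),
                     windDir = runif(6 * n, 0, 180),
                     windSp = rep(rgamma(n, 4, scale = 2.5), each = 6))
  expect_error(choice_fit(rows, c("SP")), "separation|singular")
})

test_that("fit methods expose the usual modelling interface", {
  rows <- simulate_choice_data(n_birds = 15, dp_per_bird = 10, seed = 76)
  fit <- choice_fit(rows, "wind_sp")
  expect_s3_class(fit, "choice_fit")
  expect_output(print(fit), "conditional-logit")
  s <- summary(fit)
  expect_true(all(c("coef", "se_robust", "odds_ratio") %in%
                    names(s$coefficients)))
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  p <- predict(fit)
  expect_equal(as.numeric(tapply(p, fit$design$stratum, sum)),
               rep(1, fit$n_strata), tolerance = 1e-12)
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(unname(colSums(as.matrix(sim))), rep(fit$n_strata, 2))
  r <- residuals(fit)
  expect_equal(length(r), nrow(rows))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
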