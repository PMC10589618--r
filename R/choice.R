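# Matched conditional-logit (1-of-6) habitat-selection model.
#
# Each decision point is a stratum with six alternatives (sectors), exactly
# one chosen. Conditioning on one choice per stratum eliminates all
# stratum-level effects, so the likelihood is a softmax over the choice set:
#   logL(beta) = sum_s [ x_chosen.beta - log sum_j exp(x_j.beta) ].
# Inference clusters scores on bird identity (repeated decision points per
# bird), giving a sandwich covariance; model comparison uses QIC with Pan's
# trace penalty and Akaike-type QIC weights.

#' Model term sets
#'
#' `"wind"` is `windDir * windSp` without the inestimable stratum-constant
#' `windSp` main effect (2 parameters); `"wind_sp"` is
#' `SP * windDir + SP:windSp + windDir:windSp` (5 parameters).
#'
#' @param model `"wind"`, `"wind_sp"`, or a character vector of terms drawn
#'   from `SP`, `windDir`, `SP:windDir`, `SP:windSp`, `windDir:windSp`.
#' @return character vector of term names.
#' @export
choice_terms <- function(model) {
  if (length(model) == 1 && model %in% c("wind", "wind_sp")) {
    return(switch(model,
                  wind = c("windDir", "windDir:windSp"),
                  wind_sp = c("SP", "windDir", "SP:windDir", "SP:windSp",
                              "windDir:windSp")))
  }
  allowed <- c("SP", "windDir", "SP:windDir", "SP:windSp", "windDir:windSp")
  if ("windSp" %in% model) {
    stop("windSp is constant within strata and cannot enter as a main effect")
  }
  if (!all(model %in% allowed)) {
    stop("unknown terms: ", paste(setdiff(model, allowed), collapse = ", "))
  }
  model
}

#' Build the design matrix for a choice model
#'
#' `SP` enters as the within-stratum z-score already carried by the rows;
#' `windDir` and `windSp` are centred and scaled by their global mean and
#' s.d. over all rows; interaction columns are formed after scaling.
#'
#' @param rows data.frame with columns `stratum_id`, `bird_id`, `chosen`
#'   (logical or 0/1), `SP_z`, `windDir` (degrees 0-180), `windSp` (m/s;
#'   constant within stratum).
#' @param terms character vector from [choice_terms()].
#' @param scaling optional list with `windDir_mean`, `windDir_sd`,
#'   `windSp_mean`, `windSp_sd` to reuse a previous scaling (e.g. for
#'   prediction); default computes them from `rows`.
#' @return list with `X` (matrix, one column per term), `rows` (with strata
#'   lacking complete covariates dropped), and `scaling`.
#' @export
build_design <- function(rows, terms, scaling = NULL) {
  terms <- choice_terms(terms)
  need <- c("stratum_id", "bird_id", "chosen", "SP_z", "windDir", "windSp")
  stopifnot(all(need %in% names(rows)))
  bad <- !stats::complete.cases(rows[, c("SP_z", "windDir", "windSp")])
  if (any(bad)) {
    drop_strata <- unique(rows$stratum_id[bad])
    message(sprintf("dropping %d strata with missing covariates",
                    length(drop_strata)))
    rows <- rows[!(rows$stratum_id %in% drop_strata), , drop = FALSE]
  }
  chk <- tapply(rows$chosen, rows$stratum_id, function(x) sum(x))
  if (any(chk != 1)) stop("every stratum must have exactly one chosen row")
  if (is.null(scaling)) {
    scaling <- list(windDir_mean = mean(rows$windDir),
                    windDir_sd = stats::sd(rows$windDir),
                    windSp_mean = mean(rows$windSp),
                    windSp_sd = stats::sd(rows$windSp))
  }
  wd <- (rows$windDir - scaling$windDir_mean) / scaling$windDir_sd
  ws <- (rows$windSp - scaling$windSp_mean) / scaling$windSp_sd
  sp <- rows$SP_z
  cols <- list(SP = sp, windDir = wd, `SP:windDir` = sp * wd,
               `SP:windSp` = sp * ws, `windDir:windSp` = wd * ws)
  X <- do.call(cbind, cols[terms])
  colnames(X) <- terms
  list(X = X, rows = rows, scaling = scaling)
}

# strata bookkeeping: integer stratum index per row, ordered row blocks
stratum_index <- function(stratum_id) {
  match(stratum_id, unique(stratum_id))
}

#' Conditional-logit log-likelihood
#'
#' `sum_s [x_chosen.beta - log sum_j exp(x_j.beta)]`, computed with
#' log-sum-exp stabilisation.
#'
#' @param beta coefficient vector.
#' @param X design matrix (rows = alternatives).
#' @param stratum integer stratum index per row.
#' @param chosen logical vector, exactly one TRUE per stratum.
#' @return log-likelihood.
#' @export
cond_logit_loglik <- function(beta, X, stratum, chosen) {
  if (any(tapply(chosen, stratum, sum) != 1)) {
    stop("every stratum must have exactly one chosen row")
  }
  eta <- as.numeric(X %*% beta)
  m <- ave(eta, stratum, FUN = max)
  lse <- ave(exp(eta - m), stratum, FUN = sum)
  # per-stratum logsumexp, constant within stratum:
  ls <- m + log(lse)
  sum(eta[chosen]) - sum(ls[!duplicated(stratum)])
}

# score and information pieces at beta; returns list(loglik, grad, hess,
# scores_by_stratum)
cond_logit_parts <- function(beta, X, stratum, chosen) {
  eta <- as.numeric(X %*% beta)
  m <- ave(eta, stratum, FUN = max)
  w <- exp(eta - m)
  sw <- ave(w, stratum, FUN = sum)
  p <- w / sw
  ll <- sum((eta - (m + log(sw)))[chosen])
  K <- ncol(X)
  pX <- X * p
  # per-stratum expected covariate vector
  xbar <- apply(pX, 2, function(col) ave(col, stratum, FUN = sum))
  xbar <- matrix(xbar, ncol = K)
  U_rows <- (X - xbar)[chosen, , drop = FALSE]       # per-stratum scores
  grad <- colSums(U_rows)
  # information: sum_s [ sum_j p_j x_j x_j' - xbar xbar' ]
  first <- crossprod(X, pX)
  pick <- !duplicated(stratum)
  second <- crossprod(xbar[pick, , drop = FALSE])
  info <- first - second
  list(loglik = ll, grad = grad, info = info, scores = U_rows)
}

#' Fit a matched conditional-logit choice model
#'
#' Newton-Raphson with step halving from the null start `beta = 0` (the
#' conditional-logit likelihood is concave). Naive covariance is the inverse
#' observed information; the robust covariance is the cluster sandwich with
#' per-stratum scores summed within each bird.
#'
#' @param rows covariate rows as in [build_design()].
#' @param model model name or term vector, see [choice_terms()].
#' @param scaling optional scaling constants passed to [build_design()].
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter maximum Newton iterations.
#' @return object of class `choice_fit` with components `coefficients`,
#'   `vcov_naive`, `vcov_robust`, `loglik`, `loglik_null`, `lrt`
#'   (statistic, df, p), `qic`, `concordance`, `n_strata`, `n_clusters`,
#'   `terms`, `scaling`, `design`.
#' @export
choice_fit <- function(rows, model = "wind_sp", scaling = NULL,
                       tol = 1e-8, max_iter = 50) {
  terms <- choice_terms(model)
  d <- build_design(rows, terms, scaling)
  X <- d$X
  stratum <- stratum_index(d$rows$stratum_id)
  chosen <- as.logical(d$rows$chosen)
  n_strata <- length(unique(stratum))
  if (n_strata < ncol(X)) stop("fewer strata than parameters")
  beta <- rep(0, ncol(X))
  parts <- cond_logit_parts(beta, X, stratum, chosen)
  ll0 <- parts$loglik
  for (it in seq_len(max_iter)) {
    if (sqrt(sum(parts$grad^2)) < tol) break
    step <- tryCatch(solve(parts$info, parts$grad),
                     error = function(e) stop("singular information matrix"))
    lam <- 1
    repeat {
      cand <- beta + lam * step
      if (sqrt(sum(cand^2)) > 50) {
        j <- which.max(abs(cand))
        stop(sprintf("separation detected: coefficient '%s' diverging",
                     colnames(X)[j]))
      }
      p2 <- cond_logit_parts(cand, X, stratum, chosen)
      if (p2$loglik >= parts$loglik - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) break
    }
    beta <- cand
    parts <- p2
  }
  if (sqrt(sum(parts$grad^2)) >= 1e-4) {
    warning("Newton iterations did not fully converge")
  }
  if (any(abs(beta) > 8)) {
    j <- which.max(abs(beta))
    stop(sprintf("separation detected: coefficient '%s' diverging",
                 colnames(X)[j]))
  }
  info <- parts$info
  vnaive <- solve(info)
  # cluster-robust sandwich on bird identity
  cl <- d$rows$bird_id[!duplicated(stratum)]
  Ug <- rowsum(parts$scores, group = cl)
  meat <- crossprod(as.matrix(Ug))
  vrobust <- vnaive %*% meat %*% vnaive
  ll <- parts$loglik
  stat <- 2 * (ll - ll0)
  eta <- as.numeric(X %*% beta)
  fit <- structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    vcov_naive = vnaive, vcov_robust = vrobust,
    loglik = ll, loglik_null = ll0,
    lrt = list(statistic = stat, df = ncol(X),
               p_value = stats::pchisq(stat, ncol(X), lower.tail = FALSE)),
    qic = -2 * ll + 2 * sum(diag(info %*% vrobust)),
    concordance = concordance_index(eta, stratum, chosen),
    n_strata = n_strata, n_clusters = length(unique(cl)),
    n_iter = it, terms = terms, scaling = d$scaling,
    design = list(X = X, stratum = stratum, chosen = chosen,
                  bird_id = d$rows$bird_id)
  ), class = "choice_fit")
  fit
}

#' Concordance index over within-stratum chosen/unchosen pairs
#'
#' Fraction of (chosen, unchosen) pairs within a stratum in which the chosen
#' alternative has the strictly larger linear predictor; ties (within 1e-12)
#' count one half.
#'
#' @param eta linear predictors.
#' @param stratum integer stratum index per row.
#' @param chosen logical, one TRUE per stratum.
#' @return C in [0, 1].
#' @export
concordance_index <- function(eta, stratum, chosen) {
  tot <- 0; conc <- 0
  for (s in unique(stratum)) {
    e <- eta[stratum == s]
    ch <- chosen[stratum == s]
    d <- e[ch] - e[!ch]
    conc <- conc + sum(d > 1e-12) + 0.5 * sum(abs(d) <= 1e-12)
    tot <- tot + length(d)
  }
  conc / tot
}

#' QIC weights for a set of QIC values
#'
#' Akaike-type evidence weights `exp(-Delta_i/2) / sum_j exp(-Delta_j/2)`
#' with `Delta_i = QIC_i - min(QIC)`.
#'
#' @param qic numeric vector of QIC values.
#' @return weights summing to 1.
#' @export
qic_weights <- function(qic) {
  d <- qic - min(qic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' QIC comparison table for competing fits
#'
#' @param fits named list of `choice_fit` objects fitted to identical
#'   strata.
#' @return data.frame with columns `model`, `variables`, `K`, `QIC`,
#'   `QICw`, `X2`, `C`, ordered by `QICw` (best first).
#' @export
qic_table <- function(fits) {
  ns <- vapply(fits, function(f) f$n_strata, numeric(1))
  if (length(unique(ns)) != 1) stop("fits use different strata sets")
  tab <- data.frame(
    model = names(fits),
    variables = vapply(fits, function(f) paste(f$terms, collapse = " + "),
                       character(1)),
    K = vapply(fits, function(f) length(f$coefficients), numeric(1)),
    QIC = vapply(fits, function(f) f$qic, numeric(1)),
    X2 = vapply(fits, function(f) f$lrt$statistic, numeric(1)),
    C = vapply(fits, function(f) f$concordance, numeric(1)),
    row.names = NULL
  )
  tab$QICw <- qic_weights(tab$QIC)
  tab <- tab[order(-tab$QICw), c("model", "variables", "K", "QIC", "QICw",
                                 "X2", "C")]
  rownames(tab) <- NULL
  tab
}

#' Sex-stratified model comparison
#'
#' Fits each model separately to each sex's strata and returns one QIC
#' comparison table per sex. A sex with fewer strata than the largest model
#' has parameters is skipped with a warning.
#'
#' @param rows covariate rows as in [build_design()] plus a `sex` column
#'   (constant within bird).
#' @param models character vector of model names (see [choice_terms()]).
#' @return named list of comparison tables, one per sex, each with an
#'   attached `fits` attribute.
#' @export
sex_stratified_run <- function(rows, models = c("wind_sp", "wind")) {
  stopifnot("sex" %in% names(rows))
  out <- list()
  kmax <- max(vapply(models, function(m) length(choice_terms(m)), numeric(1)))
  for (s in sort(unique(rows$sex))) {
    sub <- rows[rows$sex == s, , drop = FALSE]
    if (length(unique(sub$stratum_id)) < kmax) {
      warning(sprintf("sex '%s' has too few strata; skipped", s))
      next
    }
    fits <- lapply(models, function(m) choice_fit(sub, model = m))
    names(fits) <- models
    tab <- qic_table(fits)
    attr(tab, "fits") <- fits
    out[[as.character(s)]] <- tab
  }
  out
}
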