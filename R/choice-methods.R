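# S3 methods for choice_fit objects.

#' @export
print.choice_fit <- function(x, ...) {
  cat("Matched conditional-logit choice model (1 of 6 sectors)\n")
  cat(sprintf("  strata: %d   clusters (birds): %d   logLik: %.3f\n",
              x$n_strata, x$n_clusters, x$loglik))
  cat(sprintf("  QIC: %.2f   LRT X2(%d): %.2f   C-index: %.3f\n",
              x$qic, x$lrt$df, x$lrt$statistic, x$concordance))
  cat("Coefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Summarise a fitted choice model
#'
#' Coefficient table with naive and cluster-robust standard errors, robust
#' Wald z tests, and odds ratios with 95% confidence intervals from the
#' robust covariance.
#'
#' @param object a `choice_fit`.
#' @param ... unused.
#' @return object of class `summary.choice_fit`.
#' @export
summary.choice_fit <- function(object, ...) {
  b <- object$coefficients
  se_n <- sqrt(diag(object$vcov_naive))
  se_r <- sqrt(diag(object$vcov_robust))
  z <- b / se_r
  p <- 2 * stats::pnorm(-abs(z))
  tab <- data.frame(coef = b, se_naive = se_n, se_robust = se_r,
                    z = z, p_value = p,
                    odds_ratio = exp(b),
                    or_lo95 = exp(b - 1.96 * se_r),
                    or_hi95 = exp(b + 1.96 * se_r))
  out <- list(coefficients = tab, loglik = object$loglik,
              loglik_null = object$loglik_null, qic = object$qic,
              lrt = object$lrt, concordance = object$concordance,
              n_strata = object$n_strata, n_clusters = object$n_clusters)
  class(out) <- "summary.choice_fit"
  out
}

#' @export
print.summary.choice_fit <- function(x, ...) {
  cat("Matched conditional-logit choice model\n")
  cat(sprintf("strata: %d  clusters: %d  logLik: %.3f (null %.3f)\n",
              x$n_strata, x$n_clusters, x$loglik, x$loglik_null))
  cat(sprintf("QIC: %.2f  LRT X2(%d) = %.2f (p = %.3g)  C-index: %.3f\n",
              x$qic, x$lrt$df, x$lrt$statistic, x$lrt$p_value,
              x$concordance))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.choice_fit <- function(object, ...) object$coefficients

#' Covariance matrix of a fitted choice model
#' @param object a `choice_fit`.
#' @param type `"robust"` (cluster sandwich, default) or `"naive"` (inverse
#'   observed information).
#' @param ... unused.
#' @return covariance matrix.
#' @export
vcov.choice_fit <- function(object, type = c("robust", "naive"), ...) {
  type <- match.arg(type)
  if (type == "robust") object$vcov_robust else object$vcov_naive
}

#' @export
logLik.choice_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' Predicted sector-choice probabilities
#'
#' Softmax probabilities within each stratum of the fitted (or new) design.
#'
#' @param object a `choice_fit`.
#' @param newdata optional covariate rows as in [build_design()]; default
#'   the training rows.
#' @param ... unused.
#' @return numeric vector of probabilities, one per row, summing to 1
#'   within each stratum.
#' @export
predict.choice_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    X <- object$design$X
    stratum <- object$design$stratum
  } else {
    d <- build_design(newdata, object$terms, scaling = object$scaling)
    X <- d$X
    stratum <- stratum_index(d$rows$stratum_id)
  }
  eta <- as.numeric(X %*% object$coefficients)
  m <- ave(eta, stratum, FUN = max)
  w <- exp(eta - m)
  w / ave(w, stratum, FUN = sum)
}

#' Simulate sector choices from a fitted model
#'
#' Draws one chosen alternative per stratum from the fitted softmax
#' probabilities.
#'
#' @param object a `choice_fit`.
#' @param nsim number of replicate choice vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data.frame with one logical column per replicate, rows aligned
#'   with the training design.
#' @export
simulate.choice_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object)
  stratum <- object$design$stratum
  out <- lapply(seq_len(nsim), function(i) {
    ch <- logical(length(p))
    for (s in unique(stratum)) {
      idx <- which(stratum == s)
      ch[sample(idx, 1, prob = p[idx])] <- TRUE
    }
    ch
  })
  stats::setNames(as.data.frame(out),
                  paste0("sim_", seq_len(nsim)))
}

#' Forest plot of odds ratios
#'
#' Odds ratios with 95% robust confidence intervals on a log scale, with a
#' reference line at 1.
#'
#' @param x a `choice_fit`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.choice_fit <- function(x, ...) {
  s <- summary(x)$coefficients
  k <- nrow(s)
  graphics::plot(s$odds_ratio, k:1, log = "x",
                 xlim = range(c(s$or_lo95, s$or_hi95, 1)),
                 ylim = c(0.5, k + 0.5), yaxt = "n",
                 xlab = "odds ratio (95% CI, robust)", ylab = "",
                 pch = 19, ...)
  graphics::segments(s$or_lo95, k:1, s$or_hi95, k:1)
  graphics::abline(v = 1, col = "blue")
  graphics::axis(2, at = k:1, labels = rownames(s), las = 1)
  invisible(x)
}

#' @export
residuals.choice_fit <- function(object, ...) {
  # response residuals: observed indicator minus fitted probability
  as.numeric(object$design$chosen) - predict(object)
}
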