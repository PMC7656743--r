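# S3 methods for "retromsm" fits.

#' @export
print.retromsm <- function(x, digits = 4, ...) {
  cat("Progressive 4-state multistate Markov model (panel likelihood)\n")
  cat(sprintf("  observations: %d  (weight sum %.1f, %d covariate pattern%s)\n",
              x$nobs, x$wsum, x$n_patterns,
              if (x$n_patterns == 1) "" else "s"))
  cat(sprintf("  interval(s): %s months\n",
              paste(x$intervals, collapse = ", ")))
  cat(sprintf("  log-likelihood: %.3f   AIC: %.3f   parameters: %d\n",
              x$loglik, x$AIC, x$npar))
  cat("\nBaseline intensities (per month, at covariate reference):\n")
  q <- exp(x$alpha)
  q[x$frozen] <- 0
  print(signif(q, digits))
  if (length(x$design$colnames) > 0) {
    cat("\nCovariate coefficients (log-rate scale):\n")
    print(signif(x$beta, digits))
  }
  if (any(x$frozen))
    cat("\nFrozen (unobserved) transitions:",
        paste(names(x$frozen)[x$frozen], collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.retromsm <- function(object, ...) object$par

#' @export
vcov.retromsm <- function(object, ...) object$vcov

#' @export
logLik.retromsm <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$nobs,
            class = "logLik")
}

#' @export
summary.retromsm <- function(object, level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(pmax(diag(object$vcov), 0))
  est <- object$par
  tab <- data.frame(estimate = est, se = se,
                    lower = est - zq * se, upper = est + zq * se,
                    row.names = names(est))
  labs <- transition_labels()
  ia <- object$pidx$alpha
  rate_rows <- !object$frozen
  rates <- data.frame(
    transition = labs[rate_rows],
    rate = exp(est[ia[rate_rows]]),
    lower = exp(est[ia[rate_rows]] - zq * se[ia[rate_rows]]),
    upper = exp(est[ia[rate_rows]] + zq * se[ia[rate_rows]]),
    row.names = NULL)
  out <- list(coefficients = tab, rates = rates, level = level,
              loglik = object$loglik, AIC = object$AIC, npar = object$npar,
              nobs = object$nobs, convergence = object$convergence)
  class(out) <- "summary.retromsm"
  out
}

#' @export
print.summary.retromsm <- function(x, digits = 4, ...) {
  cat("Coefficients (log scale):\n")
  print(signif(as.matrix(x$coefficients), digits))
  cat(sprintf("\nBaseline intensities per month with %.0f%% CI:\n",
              100 * x$level))
  print(x$rates, digits = digits, row.names = FALSE)
  cat(sprintf("\nlogLik %.3f   AIC %.3f   k %d   max|grad| %.2e (restarts %d)\n",
              x$loglik, x$AIC, x$npar, x$convergence$grad_norm,
              x$convergence$restarts))
  invisible(x)
}

#' Predicted transition probability matrix
#'
#' @param object A [msm_fit()] object.
#' @param t Forecast horizon in months (default 4, the panel interval).
#' @param z Covariate profile (see [fitted_rates()]).
#' @param ... Unused.
#' @return 4 x 4 row-stochastic matrix exp(Q(z) t).
#' @export
predict.retromsm <- function(object, t = 4, z = "means", ...) {
  tpm(fitted_Q(object, z), t)
}

#' Simulate panel transitions from a fitted model
#'
#' Draws, for each observed covariate pattern, multinomial end states for
#' its panel observations from the fitted P(t; z). Useful for parametric
#' bootstrap and posterior-predictive style checks.
#'
#' @param object A [msm_fit()] object.
#' @param nsim Number of replicate datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of `nsim` data.frames with columns `from`, `to`, `t`,
#'   `n` (simulated counts per cell).
#' @export
simulate.retromsm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  agg <- object$agg
  reps <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    rows <- list()
    for (ip in seq_along(agg$patterns)) {
      pat <- agg$patterns[[ip]]
      P <- tpm(fitted_Q(object, pat$z), pat$t)
      cc <- agg$cells[agg$cells$pattern == ip, , drop = FALSE]
      for (f in unique(cc$from)) {
        n_f <- round(sum(cc$w[cc$from == f]))
        if (n_f <= 0) next
        draw <- stats::rmultinom(1, n_f, P[f, ])
        keep <- draw[, 1] > 0
        rows[[length(rows) + 1]] <- data.frame(
          from = f, to = which(keep), t = pat$t, n = draw[keep, 1])
      }
    }
    reps[[r]] <- do.call(rbind, rows)
  }
  reps
}

#' Pearson residuals of the fitted transition counts
#'
#' Observed minus expected counts per covariate-pattern cell, scaled by the
#' binomial standard deviation.
#'
#' @param object A [msm_fit()] object.
#' @param ... Unused.
#' @return Data.frame with columns `pattern`, `from`, `to`, `observed`,
#'   `expected`, `pearson`.
#' @export
residuals.retromsm <- function(object, ...) {
  agg <- object$agg
  out <- list()
  for (ip in seq_along(agg$patterns)) {
    pat <- agg$patterns[[ip]]
    P <- tpm(fitted_Q(object, pat$z), pat$t)
    cc <- agg$cells[agg$cells$pattern == ip, , drop = FALSE]
    for (f in unique(cc$from)) {
      n_f <- sum(cc$w[cc$from == f])
      for (j in which(P[f, ] > 0 | seq_len(4) %in% cc$to[cc$from == f])) {
        obs <- sum(cc$w[cc$from == f & cc$to == j])
        exp_ <- n_f * P[f, j]
        v <- n_f * P[f, j] * (1 - P[f, j])
        out[[length(out) + 1]] <- data.frame(
          pattern = ip, from = f, to = j, observed = obs, expected = exp_,
          pearson = if (v > 0) (obs - exp_) / sqrt(v) else 0)
      }
    }
  }
  do.call(rbind, out)
}

#' Plot fitted state-occupancy curves
#'
#' Probability of occupying each state over time, starting from never use,
#' at a covariate profile.
#'
#' @param x A [msm_fit()] object.
#' @param t_max Horizon in months.
#' @param z Covariate profile.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the matrix of occupancy probabilities.
#' @export
plot.retromsm <- function(x, t_max = 48, z = "means", ...) {
  Q <- fitted_Q(x, z)
  tt <- seq(0, t_max, length.out = 97)
  occ <- t(vapply(tt, function(s) tpm(Q, s)[1, ], numeric(4)))
  graphics::matplot(tt, occ, type = "l", lty = 1, lwd = 2,
                    xlab = "months since baseline",
                    ylab = "occupancy probability from never use",
                    col = c("grey40", "firebrick", "steelblue", "purple"),
                    ...)
  graphics::legend("right", transition_structure()$labels, lty = 1, lwd = 2,
                   col = c("grey40", "firebrick", "steelblue", "purple"),
                   bty = "n")
  invisible(occ)
}
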