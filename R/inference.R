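# Reported quantities derived from a fit: transition-intensity ratios
# (delta method on the log scale), transition-probability matrices with
# simulation-based confidence intervals, and the covariate-ladder model
# comparison.

parse_transition <- function(lab) {
  labs <- transition_labels()
  if (is.numeric(lab) && length(lab) == 2) lab <- paste0(lab[1], "->", lab[2])
  if (!lab %in% labs)
    stop("transition '", lab, "' is not in the allowed structure (",
         paste(labs, collapse = ", "), ")")
  lab
}

# contrast vector c such that log q_lab(z) = c' theta (free parameters)
log_rate_contrast <- function(fit, lab, z) {
  k <- match(lab, transition_labels())
  if (fit$frozen[k]) stop("transition ", lab, " has a frozen intercept")
  cvec <- numeric(fit$npar)
  cvec[fit$pidx$alpha[k]] <- 1
  p <- length(fit$design$colnames)
  if (p > 0 && length(z) > 0) {
    idx <- fit$pidx$beta[k, ]
    # shared coefficients share indices; accumulation handles both layouts
    for (j in seq_len(p)) cvec[idx[j]] <- cvec[idx[j]] + z[j]
  }
  cvec
}

#' Transition intensity ratio with delta-method confidence interval
#'
#' The TIR q_num(z) / q_den(z) compares the instantaneous risks of two
#' transitions and is interpreted as a relative risk, e.g. the risk of
#' cigarette initiation among ENDS ever users ("3->4") versus never users
#' ("1->2"). log TIR is a linear combination of the model parameters, so
#' its standard error follows from the fitted covariance and the CI is
#' exponentiated.
#'
#' @param fit A [msm_fit()] object.
#' @param num,den Transition labels ("1->2", "1->3", "1->4", "2->4",
#'   "3->4") or length-2 integer vectors.
#' @param z Covariate profile (see [fitted_rates()]); with
#'   transition-specific coefficients the profile matters and is reported
#'   alongside the estimate.
#' @param level Confidence level, default 0.95.
#' @return List of class "retromsm_tir": `estimate`, `lower`, `upper`,
#'   `log_se`, `num`, `den`, `z`, `level`.
#' @examples
#' fit <- msm_fit(build_cohort(generate_table2_fixture()))
#' tir(fit, "3->4", "1->2")
#' @export
tir <- function(fit, num, den, z = "means", level = 0.95) {
  num <- parse_transition(num); den <- parse_transition(den)
  zz <- resolve_profile(fit, z)
  cvec <- log_rate_contrast(fit, num, zz) - log_rate_contrast(fit, den, zz)
  est_log <- sum(cvec * fit$par)
  se <- sqrt(max(0, as.numeric(t(cvec) %*% fit$vcov %*% cvec)))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(estimate = exp(est_log),
                 lower = exp(est_log - zq * se),
                 upper = exp(est_log + zq * se),
                 log_se = se, num = num, den = den, z = zz, level = level),
            class = "retromsm_tir")
}

#' @export
print.retromsm_tir <- function(x, digits = 3, ...) {
  cat(sprintf("TIR %s vs %s: %.*g (%.0f%% CI: %.*g-%.*g)\n",
              x$num, x$den, digits, x$estimate, 100 * x$level,
              digits, x$lower, digits, x$upper))
  invisible(x)
}

#' Transition probabilities at time t with simulation confidence intervals
#'
#' Point estimates are exp(Q(z) t) at the fitted parameters. Confidence
#' intervals come from parametric simulation: B parameter vectors are drawn
#' from the asymptotic normal (mean = estimates, covariance = fitted
#' covariance), P is recomputed for each, and percentile intervals are
#' taken per cell. Structural zeros are reported as exact 0 without a CI.
#'
#' @param fit A [msm_fit()] object.
#' @param t Horizon in months (default 4).
#' @param z Covariate profile; the default `"means"` evaluates at the
#'   cohort means of the design columns, matching the convention of
#'   reporting model estimates "at the mean of all covariates".
#' @param B Number of simulation draws, default 1000.
#' @param level Confidence level, default 0.95.
#' @param seed Seed for the draws (recorded in the result), default 1.
#' @return List of class "retromsm_tp": `estimate`, `lower`, `upper`
#'   (4 x 4 matrices; bounds `NA` on structural zeros and the absorbing
#'   diagonal), plus `t`, `z`, `B`, `level`, `seed`.
#' @export
tp_report <- function(fit, t = 4, z = "means", B = 1000, level = 0.95,
                      seed = 1L) {
  stopifnot(t >= 0, B >= 2)
  zz <- resolve_profile(fit, z)
  est <- tpm(fitted_Q_profile(fit, fit$par, zz), t)
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("tp_report: covariance is not positive semi-definite; refit the model")
  set.seed(seed)
  draws <- MASS::mvrnorm(B, mu = fit$par, Sigma = fit$vcov)
  sims <- array(NA_real_, c(B, 4, 4))
  for (b in seq_len(B)) {
    sims[b, , ] <- tpm(fitted_Q_profile(fit, draws[b, ], zz), t)
  }
  al <- (1 - level) / 2
  lower <- apply(sims, c(2, 3), stats::quantile, probs = al)
  upper <- apply(sims, c(2, 3), stats::quantile, probs = 1 - al)
  free_cell <- est > 0 & est < 1
  lower[!free_cell] <- NA; upper[!free_cell] <- NA
  dn <- list(baseline = 1:4, end = 1:4)
  dimnames(est) <- dimnames(lower) <- dimnames(upper) <- dn
  structure(list(estimate = est, lower = lower, upper = upper,
                 t = t, z = zz, B = B, level = level, seed = seed),
            class = "retromsm_tp")
}

# Q from an arbitrary free-parameter vector at profile z (used by the
# simulation CIs, where theta is a draw rather than the estimate)
fitted_Q_profile <- function(fit, theta, z) {
  pb <- unpack_par(theta, fit$pidx, fit$frozen)
  q <- rates_at(pb$alpha, pb$Beta, z)
  intensity_matrix(q[1], q[2], q[3], q[4], q[5])
}

#' @export
print.retromsm_tp <- function(x, digits = 4, ...) {
  cat(sprintf("Transition probabilities at t = %g months (%%, %.0f%% CI, B = %d):\n",
              x$t, 100 * x$level, x$B))
  fmt <- function(i, j) {
    if (x$estimate[i, j] == 0 && i != j) return("-")
    if (is.na(x$lower[i, j]))
      return(sprintf("%.*f", 2, 100 * x$estimate[i, j]))
    sprintf("%.2f (%.2f-%.2f)", 100 * x$estimate[i, j],
            100 * x$lower[i, j], 100 * x$upper[i, j])
  }
  m <- matrix("", 4, 4, dimnames = list(baseline = 1:4, end = 1:4))
  for (i in 1:4) for (j in 1:4) m[i, j] <- fmt(i, j)
  print(m, quote = FALSE)
  invisible(x)
}

#' Covariate-ladder model comparison
#'
#' Fits the nested sequence null, +sex, +grade, +alcohol, +paternal
#' education (covariates added one at a time to the null model) and
#' tabulates -2 log-likelihood, parameter count, AIC, and the likelihood
#' ratio test against the previous model in the ladder.
#'
#' @param cohort Cohort data.frame.
#' @param ladder Character vector naming the covariates to add in order;
#'   any of "sex", "grade", "alcohol", "pedu".
#' @param shared_covariates Passed to [msm_fit()].
#' @param control Passed to [msm_fit()].
#' @return Data.frame with one row per model (`model`, `k`, `minus2LL`,
#'   `AIC`, `LRT_stat`, `LRT_df`, `LRT_p`); a failed fit is flagged with
#'   `NA` values and the ladder continues.
#' @export
compare_models <- function(cohort,
                           ladder = c("sex", "grade", "alcohol", "pedu"),
                           shared_covariates = FALSE, control = list()) {
  terms_map <- c(sex = "sex", grade = "baseline_grade",
                 alcohol = "ever_alcohol_baseline",
                 pedu = "paternal_edu_3level")
  stopifnot(all(ladder %in% names(terms_map)))
  labels <- c("null", paste0("+", ladder))
  forms <- c(list(NULL), lapply(seq_along(ladder), function(i)
    stats::reformulate(terms_map[ladder[seq_len(i)]])))
  rows <- list()
  prev <- NULL
  for (i in seq_along(forms)) {
    f <- tryCatch(msm_fit(cohort, forms[[i]],
                          shared_covariates = shared_covariates,
                          control = control),
                  error = function(e) NULL)
    if (is.null(f)) {
      rows[[i]] <- data.frame(model = labels[i], k = NA, minus2LL = NA,
                              AIC = NA, LRT_stat = NA, LRT_df = NA,
                              LRT_p = NA)
      next
    }
    lrt_stat <- lrt_df <- lrt_p <- NA_real_
    if (!is.null(prev)) {
      lrt_stat <- max(0, -2 * (prev$loglik - f$loglik))
      lrt_df <- f$npar - prev$npar
      lrt_p <- stats::pchisq(lrt_stat, lrt_df, lower.tail = FALSE)
    }
    rows[[i]] <- data.frame(model = labels[i], k = f$npar,
                            minus2LL = -2 * f$loglik, AIC = f$AIC,
                            LRT_stat = lrt_stat, LRT_df = lrt_df,
                            LRT_p = lrt_p)
    prev <- f
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
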