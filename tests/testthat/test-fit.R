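test_that("panel log-likelihood has the elementary properties", {
  # one observation absorbed in state 4 contributes log 1 = 0
  co <- data.frame(baseline_state = 4L, end_state = 4L,
                   interval_months = 4, weight = 1)
  fit0 <- suppressWarnings(tryCatch(msm_fit(co), error = function(e) e))
  expect_s3_class(fit0, "error")  # nothing identifiable from stayers alone

  counts <- data.frame(baseline = c(1, 1, 1, 1, 2, 2, 3, 3, 4),
                       end      = c(1, 2, 3, 4, 2, 4, 3, 4, 4),
                       n        = c(500, 20, 5, 4, 80, 10, 30, 4, 50))
  co <- cohort_from_counts(counts)
  f <- msm_fit(co)
  nll <- retromsm:::panel_negloglik
  # additivity: k identical observations scale the likelihood by k
  co3 <- co[rep(seq_len(nrow(co)), 3), ]
  des <- retromsm:::build_design(co3, NULL)
  agg3 <- retromsm:::aggregate_panel(des$X, co3$interval_months,
                                     co3$baseline_state, co3$end_state,
                                     rep(1, nrow(co3)))
  expect_equal(nll(f$par, agg3, f$pidx, f$frozen), 3 * -f$loglik,
               tolerance = 1e-8)
  # absorbing-state cells contribute nothing
  agg_abs <- retromsm:::aggregate_panel(matrix(0, 1, 0), 4, 4L, 4L, 10)
  expect_equal(nll(f$par, agg_abs, f$pidx, f$frozen), 0)
})

test_that("structurally impossible observations are a data error", {
  co <- data.frame(baseline_state = c(1L, 2L), end_state = c(2L, 1L),
                   interval_months = 4, weight = 1)
  expect_error(msm_fit(co), "impossible")
})

test_that("saturated no-covariate fit equals the empirical proportions", {
  counts <- data.frame(baseline = c(1, 1, 1, 1, 2, 2, 3, 3, 4),
                       end      = c(1, 2, 3, 4, 2, 4, 3, 4, 4),
                       n        = c(2000, 60, 12, 9, 300, 40, 100, 13, 150))
  co <- cohort_from_counts(counts)
  f <- msm_fit(co)
  P <- predict(f, 4)
  emp <- matrix(0, 4, 4)
  emp[cbind(counts$baseline, counts$end)] <- counts$n
  emp <- emp / rowSums(emp)
  expect_lt(max(abs(P - emp)), 1e-6)
  # and equals the matrix-log inversion oracle
  Qo <- invert_single_interval(emp, 4)
  expect_lt(max(abs(fitted_Q(f) - Qo)), 1e-6)
  # likelihood at the optimum is the multinomial maximum
  nonzero <- counts$n > 0
  ni <- stats::ave(counts$n, counts$baseline, FUN = sum)
  expect_equal(f$loglik,
               sum((counts$n * log(counts$n / ni))[counts$baseline != 4]),
               tolerance = 1e-8)
})

test_that("integer weights are equivalent to row expansion", {
  counts <- data.frame(baseline = c(1, 1, 1, 1, 2, 2, 3, 3),
                       end      = c(1, 2, 3, 4, 2, 4, 3, 4),
                       n        = c(800, 25, 6, 5, 120, 18, 40, 6))
  expanded <- cohort_from_counts(counts)
  weighted <- data.frame(baseline_state = counts$baseline,
                         end_state = counts$end, interval_months = 4,
                         weight = counts$n)
  fe <- msm_fit(expanded)
  fw <- msm_fit(weighted)
  expect_equal(fw$loglik, fe$loglik, tolerance = 1e-8)
  expect_equal(fw$alpha, fe$alpha, tolerance = 1e-6)
})

test_that("likelihood is invariant to the time unit", {
  counts <- data.frame(baseline = c(1, 1, 1, 1, 2, 2, 3, 3),
                       end      = c(1, 2, 3, 4, 2, 4, 3, 4),
                       n        = c(900, 30, 8, 6, 150, 20, 50, 7))
  months <- cohort_from_counts(counts, t = 4)
  years <- cohort_from_counts(counts, t = 4 / 12)
  fm <- msm_fit(months)
  fy <- msm_fit(years)
  expect_equal(fm$loglik, fy$loglik, tolerance = 1e-7)
  # rates rescale by exactly the unit change: alpha shifts by log 12
  expect_equal(fy$alpha - fm$alpha, rep(log(12), 5),
               tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("unobserved transitions are frozen with a warning, not divergent", {
  counts <- data.frame(baseline = c(1, 1, 2, 2, 3),
                       end      = c(1, 2, 2, 4, 3),
                       n        = c(500, 20, 100, 15, 30))
  co <- cohort_from_counts(counts)
  expect_warning(f <- msm_fit(co), "frozen")
  expect_true(f$frozen[["1->3"]])
  expect_true(f$frozen[["3->4"]])
  expect_equal(unname(f$alpha[c("1->3", "3->4")]), rep(log(1e-12), 2))
  expect_false(any(f$frozen[c("1->2", "2->4")]))
  expect_true(is.finite(f$loglik))
})

test_that("log-linear covariate effects are recovered on synthetic data", {
  cfg <- generator_config(
    n_subjects = 30000,
    baseline_log_intensities = log(DESK_RATES),
    covariate_effects = list("1->2" = c(sex_female = -0.8)),
    seed = 31)
  ds <- generate_dataset(cfg)
  cohort <- build_cohort(ds$survey)
  f <- msm_fit(cohort, ~ sex)
  b <- f$beta["1->2", "sexfemale"]
  se <- sqrt(diag(f$vcov))[["1->2:sexfemale"]]
  expect_lt(abs(b - (-0.8)), 3 * se)
  expect_lt(se, 0.3)
})

test_that("Wald intervals cover the generating log-intensities", {
  truth <- log(RECOVERY_RATES)
  hits <- matrix(FALSE, 6, 5)
  for (r in 1:6) {
    cfg <- generator_config(n_subjects = 20000,
                            baseline_log_intensities = truth,
                            seed = 400 + r)
    ds <- generate_dataset(cfg)
    f <- msm_fit(build_cohort(ds$survey))
    se <- sqrt(diag(f$vcov))[1:5]
    hits[r, ] <- abs(f$alpha - truth) <= stats::qnorm(0.975) * se
  }
  # 30 nominal-95% intervals: allow a few misses
  expect_gte(sum(hits), 26)
})

test_that("adding a null covariate rarely moves -2 logLik past chi-square", {
  # Wilks at desk scale: true sex effect is zero
  stats_ <- numeric(6)
  for (r in 1:6) {
    cfg <- generator_config(n_subjects = 8000,
                            baseline_log_intensities = log(DESK_RATES),
                            seed = 500 + r)
    ds <- generate_dataset(cfg)
    cohort <- build_cohort(ds$survey)
    f0 <- msm_fit(cohort)
    f1 <- msm_fit(cohort, ~ sex)
    stats_[r] <- max(0, 2 * (f1$loglik - f0$loglik))
  }
  crit <- stats::qchisq(0.95, df = 5)
  expect_gte(sum(stats_ < crit), 5)
})

test_that("simulate, residuals and plot methods are coherent with the fit", {
  f <- msm_fit(build_cohort(generate_table2_fixture()))
  s <- simulate(f, nsim = 2, seed = 3)
  expect_length(s, 2)
  expect_equal(sum(s[[1]]$n), 59796)  # row totals preserved
  reach <- transition_structure()$reachable
  expect_true(all(reach[cbind(s[[1]]$from, s[[1]]$to)]))
  # saturated fit: observed = expected, residuals vanish
  r <- residuals(f)
  expect_lt(max(abs(r$pearson)), 1e-3)
  expect_equal(sum(r$observed), sum(r$expected), tolerance = 1e-8)
  grDevices::pdf(NULL)
  occ <- plot(f, t_max = 24)
  grDevices::dev.off()
  expect_equal(rowSums(occ), rep(1, nrow(occ)), tolerance = 1e-8)
  expect_true(all(diff(occ[, 1]) <= 1e-12))  # never-use occupancy declines
})

test_that("fit is reproducible and reports convergence diagnostics", {
  cfg <- generator_config(n_subjects = 5000, seed = 77)
  cohort <- build_cohort(generate_dataset(cfg)$survey)
  f1 <- msm_fit(cohort)
  f2 <- msm_fit(cohort)
  expect_identical(coef(f1), coef(f2))
  expect_equal(f1$convergence$code, 0)
  expect_lt(f1$convergence$grad_norm, 1e-2)
  expect_equal(f1$AIC, -2 * f1$loglik + 2 * f1$npar)
  expect_equal(AIC(f1), f1$AIC)
  v <- vcov(f1)
  expect_equal(v, t(v))
  expect_true(all(eigen(v, only.values = TRUE)$values > -1e-10))
})
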