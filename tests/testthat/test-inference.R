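fixture_fit <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- msm_fit(build_cohort(generate_table2_fixture()))
    memo
  }
})

test_that("the identity contrast gives TIR 1 with a degenerate interval", {
  f <- fixture_fit()
  r <- tir(f, "1->2", "1->2")
  expect_equal(r$estimate, 1)
  expect_equal(r$lower, 1)
  expect_equal(r$upper, 1)
})

test_that("TIR equals the intensity ratio from the inversion oracle", {
  f <- fixture_fit()
  emp <- attr(build_cohort(generate_table2_fixture()), "transition_table")
  emp[4, 4] <- max(emp[4, 4], 1)
  Phat <- emp / rowSums(emp)
  Qo <- invert_single_interval(Phat, 4)
  r <- tir(f, "3->4", "1->2")
  expect_equal(r$estimate, Qo[3, 4] / Qo[1, 2], tolerance = 1e-5)
  expect_true(r$lower <= r$estimate && r$estimate <= r$upper)
  expect_gt(r$lower, 0)
  r2 <- tir(f, "2->4", "1->3")
  expect_equal(r2$estimate, Qo[2, 4] / Qo[1, 3], tolerance = 1e-5)
  expect_error(tir(f, "2->3", "1->2"), "not in the allowed structure")
})

test_that("TIR is invariant to the time unit of the fit", {
  counts <- data.frame(baseline = c(1, 1, 1, 1, 2, 2, 3, 3),
                       end      = c(1, 2, 3, 4, 2, 4, 3, 4),
                       n        = c(900, 30, 8, 6, 150, 20, 50, 7))
  fm <- msm_fit(cohort_from_counts(counts, t = 4))
  fy <- msm_fit(cohort_from_counts(counts, t = 4 / 12))
  rm_ <- tir(fm, "3->4", "1->2")
  ry <- tir(fy, "3->4", "1->2")
  expect_equal(rm_$estimate, ry$estimate, tolerance = 1e-5)
  expect_equal(rm_$log_se, ry$log_se, tolerance = 1e-3)
})

test_that("TIR recovery: CI covers a generating ratio of 6.8", {
  # ratio q(3->4)/q(1->2) = 0.0272/0.004 = 6.8 in the generator
  covered <- 0
  for (r in 1:5) {
    cfg <- generator_config(n_subjects = 20000,
                            baseline_log_intensities = log(RECOVERY_RATES),
                            seed = 600 + r)
    f <- msm_fit(build_cohort(generate_dataset(cfg)$survey))
    ci <- tir(f, "3->4", "1->2")
    covered <- covered + (ci$lower <= 6.8 && 6.8 <= ci$upper)
  }
  expect_gte(covered, 4)
})

test_that("shared coefficients make the TIR profile-free", {
  cfg <- generator_config(n_subjects = 8000, seed = 61,
                          covariate_effects = list("1->2" = c(sex_female = 0.4)))
  cohort <- build_cohort(generate_dataset(cfg)$survey)
  f <- msm_fit(cohort, ~ sex, shared_covariates = TRUE)
  r0 <- tir(f, "3->4", "1->2", z = c(sexfemale = 0))
  r1 <- tir(f, "3->4", "1->2", z = c(sexfemale = 1))
  expect_equal(r0$estimate, r1$estimate)
  expect_equal(r0$log_se, r1$log_se)
  # with transition-specific coefficients the profile matters
  ft <- msm_fit(cohort, ~ sex)
  s0 <- tir(ft, "3->4", "1->2", z = c(sexfemale = 0))
  s1 <- tir(ft, "3->4", "1->2", z = c(sexfemale = 1))
  expect_false(isTRUE(all.equal(s0$estimate, s1$estimate)))
})

test_that("tp_report at t = 0 is the identity with degenerate intervals", {
  f <- fixture_fit()
  tp <- tp_report(f, t = 0, B = 50, seed = 2)
  expect_equal(tp$estimate, diag(4), ignore_attr = TRUE)
  expect_true(all(is.na(tp$lower)))  # no free cells at t = 0
})

test_that("tp_report reproduces the saturated fixture proportions", {
  f <- fixture_fit()
  tp <- tp_report(f, t = 4, B = 400, seed = 3)
  expect_equal(tp$estimate[1, 1], 50836 / 51905, tolerance = 1e-4)
  expect_equal(tp$estimate[2, 2], 3883 / 4399, tolerance = 1e-4)
  expect_equal(unname(rowSums(tp$estimate)), rep(1, 4), tolerance = 1e-10)
  # structural zeros are exact with no interval
  expect_equal(tp$estimate[2, 3], 0)
  expect_true(is.na(tp$lower[2, 3]))
  # simulation intervals bracket the point estimates on free cells
  free <- tp$estimate > 0 & tp$estimate < 1
  expect_true(all(tp$lower[free] <= tp$estimate[free] + 1e-9))
  expect_true(all(tp$upper[free] >= tp$estimate[free] - 1e-9))
  # reproducible given the recorded seed
  tp2 <- tp_report(f, t = 4, B = 400, seed = 3)
  expect_identical(tp$lower, tp2$lower)
})

test_that("TP rows sum to 1 at any covariate profile", {
  cfg <- generator_config(n_subjects = 10000, seed = 41,
                          covariate_effects = list("1->2" = c(sex_female = 0.5)))
  cohort <- build_cohort(generate_dataset(cfg)$survey)
  f <- msm_fit(cohort, ~ sex)
  for (z in list("means", "zero", c(sexfemale = 1))) {
    P <- predict(f, 4, z = z)
    expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-10)
  }
})

test_that("estimates converge to generator truth as n grows", {
  truth <- log(RECOVERY_RATES)
  rmse_at <- function(n, seeds) {
    errs <- sapply(seeds, function(s) {
      cfg <- generator_config(n_subjects = n, baseline_log_intensities = truth,
                              seed = s)
      f <- msm_fit(build_cohort(generate_dataset(cfg)$survey))
      f$alpha - truth
    })
    sqrt(mean(errs^2))
  }
  expect_lt(rmse_at(40000, 701:703), rmse_at(5000, 701:703))
})

test_that("the covariate ladder has increasing df and nonincreasing -2LL", {
  cfg <- generator_config(
    n_subjects = 12000, seed = 51,
    baseline_log_intensities = log(c("1->2" = 0.006, "1->3" = 0.001,
                                     "1->4" = 0.001, "2->4" = 0.03,
                                     "3->4" = 0.03)),
    covariate_effects = list("1->2" = c(sex_female = -0.6, alcohol = 0.8)))
  cohort <- build_cohort(generate_dataset(cfg)$survey)
  tab <- compare_models(cohort)
  expect_equal(tab$model, c("null", "+sex", "+grade", "+alcohol", "+pedu"))
  expect_equal(tab$k[1], 5)  # five allowed transitions in the null model
  expect_true(all(diff(tab$k) > 0))
  expect_true(all(diff(tab$minus2LL) <= 1e-6))
  expect_true(all(tab$LRT_p[-1] >= 0 & tab$LRT_p[-1] <= 1))
})

test_that("a real sex effect is detected by AIC more often than not", {
  wins <- 0
  for (r in 1:5) {
    cfg <- generator_config(
      n_subjects = 10000, seed = 800 + r,
      baseline_log_intensities = log(c("1->2" = 0.008, "1->3" = 0.001,
                                       "1->4" = 0.001, "2->4" = 0.03,
                                       "3->4" = 0.03)),
      covariate_effects = list("1->2" = c(sex_female = -0.9),
                               "2->4" = c(sex_female = -0.9)))
    cohort <- build_cohort(generate_dataset(cfg)$survey)
    f0 <- msm_fit(cohort)
    f1 <- msm_fit(cohort, ~ sex)
    wins <- wins + (f1$AIC < f0$AIC)
  }
  expect_gte(wins, 4)
})
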