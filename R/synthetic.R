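# Synthetic KYRBS-like survey generator.
#
# The real survey microdata are restricted-access, so every downstream stage
# is validated against data simulated from known ground-truth intensities:
# a progressive continuous-time Markov chain over the four ever-use states,
# run forward from the start of grade 1 with subject-specific log-linear
# intensities, then "asked" the survey questions (grade at first use,
# past-30-day frequency) to produce records in the questionnaire schema.

FREQ_BANDS <- c("none", "1-2", "3-5", "6-9", "10-19", "20-29", "everyday")

#' Configuration for the synthetic survey generator
#'
#' @param n_subjects Number of respondents to simulate.
#' @param baseline_log_intensities Named numeric vector of log rates per
#'   month for the five allowed transitions (names "1->2", "1->3", "1->4",
#'   "2->4", "3->4"). `-Inf` means the transition never fires. Defaults are
#'   desk-scale rates of the order seen in adolescent initiation data.
#' @param covariate_effects Named list: one element per transition label,
#'   each a named numeric vector of log-rate coefficients over the design
#'   columns `sex_female`, `grade_c` (current grade minus 9.5), `alcohol`
#'   (ever alcohol at baseline), `pedu_high`, `pedu_unknown`. `NULL` means
#'   no covariate effects.
#' @param p_female Probability of female sex.
#' @param grade_probs Probabilities over current school grades 7..12.
#' @param pedu_probs Probabilities over the three paternal-education levels
#'   (college or higher, high school or lower, unknown/NA).
#' @param alcohol_rate Hazard (per month) of alcohol initiation.
#' @param emission_probs List with elements `cig` and `ends`: probabilities
#'   over the seven past-30-day bands ("none", "1-2", ..., "everyday") for a
#'   respondent who is an ever-user of that product at survey time. Never
#'   users always answer "none".
#' @param missingness_rates Named vector with entries `cig_grade`,
#'   `ends_grade`, `paternal_edu`: MCAR probabilities of blanking the
#'   initiation grade (the ever flag is kept) or paternal education.
#' @param preschool_months Length of the pre-school exposure window before
#'   grade 1 during which initiation can occur (reported as "before entering
#'   elementary school"); 0 disables it.
#' @param seed Integer seed; [generate_dataset()] is deterministic given it.
#' @return A list of class "generator_config".
#' @export
generator_config <- function(n_subjects = 2000,
                             baseline_log_intensities = log(c(
                               "1->2" = 0.004, "1->3" = 0.0006,
                               "1->4" = 0.0006, "2->4" = 0.025,
                               "3->4" = 0.025)),
                             covariate_effects = NULL,
                             p_female = 0.48,
                             grade_probs = rep(1 / 6, 6),
                             pedu_probs = c(college_or_higher = 0.537,
                                            high_school_or_lower = 0.251,
                                            unknown_NA = 0.212),
                             alcohol_rate = 0.0045,
                             emission_probs = list(
                               cig  = c(0.55, 0.13, 0.08, 0.06, 0.06, 0.05, 0.07),
                               ends = c(0.65, 0.12, 0.07, 0.05, 0.04, 0.03, 0.04)),
                             missingness_rates = c(cig_grade = 0,
                                                   ends_grade = 0,
                                                   paternal_edu = 0),
                             preschool_months = 0,
                             seed = 1L) {
  labs <- transition_labels()
  if (is.null(names(baseline_log_intensities)))
    names(baseline_log_intensities) <- labs
  stopifnot(setequal(names(baseline_log_intensities), labs))
  rates <- exp(baseline_log_intensities[labs])
  if (any(is.na(rates) | rates == Inf))
    stop("generator_config: baseline intensities must exponentiate to finite nonnegative rates")
  stopifnot(n_subjects >= 1, p_female >= 0, p_female <= 1,
            length(grade_probs) == 6, all(grade_probs >= 0),
            abs(sum(grade_probs) - 1) < 1e-8 || sum(grade_probs) > 0,
            length(pedu_probs) == 3, all(pedu_probs >= 0),
            alcohol_rate >= 0, preschool_months >= 0)
  for (p in emission_probs) {
    stopifnot(length(p) == length(FREQ_BANDS), all(p >= 0),
              abs(sum(p) - 1) < 1e-6)
  }
  stopifnot(all(missingness_rates >= 0), all(missingness_rates <= 1))
  if (!is.null(covariate_effects)) {
    stopifnot(all(names(covariate_effects) %in% labs))
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 baseline_log_intensities = baseline_log_intensities[labs],
                 covariate_effects = covariate_effects,
                 p_female = p_female,
                 grade_probs = grade_probs / sum(grade_probs),
                 pedu_probs = pedu_probs / sum(pedu_probs),
                 alcohol_rate = alcohol_rate,
                 emission_probs = emission_probs,
                 missingness_rates = missingness_rates,
                 preschool_months = preschool_months,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# per-subject rates: exp(log q0 + beta . z); z columns fixed by design
subject_rates <- function(config, z) {
  labs <- transition_labels()
  n <- nrow(z)
  q <- matrix(rep(exp(config$baseline_log_intensities), each = n), n, 5,
              dimnames = list(NULL, labs))
  if (!is.null(config$covariate_effects)) {
    for (lab in names(config$covariate_effects)) {
      b <- config$covariate_effects[[lab]]
      stopifnot(all(names(b) %in% colnames(z)))
      q[, lab] <- q[, lab] * exp(as.vector(z[, names(b), drop = FALSE] %*% b))
    }
  }
  if (any(!is.finite(q))) stop("subject_rates: non-finite intensity")
  q
}

# exponential draw that tolerates rate 0 (-> Inf)
rexp0 <- function(n, rate) stats::rexp(n) / rate

#' Simulate ground-truth use trajectories
#'
#' Runs the progressive chain forward from state 1 (never use) at the start
#' of grade 1, by competing exponential clocks on the allowed transitions
#' out of the current state, with subject-specific intensities
#' q(z) = exp(log q0 + beta.z). The survey observes each subject 4 months
#' into their current grade; the baseline is the end of the previous grade.
#'
#' @param config A [generator_config()].
#' @param covariates Optional data.frame with columns `sex`, `grade`,
#'   `paternal_edu3`, `alcohol_time` to use instead of drawing them.
#' @return A data.frame (one row per subject) with covariates, initiation
#'   times in months since the start of grade 1 (`NA` if none by survey
#'   time), `baseline_time`, `survey_time`, and true states
#'   `state_baseline`, `state_survey`.
#' @note Uses the current RNG stream; seed via [generate_dataset()] or
#'   `set.seed()` for reproducibility.
#' @export
simulate_trajectories <- function(config, covariates = NULL) {
  n <- config$n_subjects
  if (is.null(covariates)) {
    sex <- ifelse(stats::runif(n) < config$p_female, "female", "male")
    grade <- sample(7:12, n, replace = TRUE, prob = config$grade_probs)
    pedu3 <- sample(names(config$pedu_probs), n, replace = TRUE,
                    prob = config$pedu_probs)
    alcohol_time <- rexp0(n, config$alcohol_rate)
  } else {
    stopifnot(nrow(covariates) == n)
    sex <- covariates$sex; grade <- covariates$grade
    pedu3 <- covariates$paternal_edu3; alcohol_time <- covariates$alcohol_time
  }
  baseline_time <- 12 * (grade - 1)
  survey_time <- baseline_time + 4
  z <- cbind(sex_female = as.numeric(sex == "female"),
             grade_c = grade - 9.5,
             alcohol = as.numeric(alcohol_time <= baseline_time),
             pedu_high = as.numeric(pedu3 == "high_school_or_lower"),
             pedu_unknown = as.numeric(pedu3 == "unknown_NA"))
  q <- subject_rates(config, z)
  t0 <- -config$preschool_months
  a1 <- q[, "1->2"] + q[, "1->3"] + q[, "1->4"]
  t_exit1 <- t0 + rexp0(n, a1)
  # destination out of state 1 (competing risks)
  u <- stats::runif(n) * a1
  dest <- ifelse(u < q[, "1->2"], 2L,
                 ifelse(u < q[, "1->2"] + q[, "1->3"], 3L, 4L))
  dest[!is.finite(t_exit1)] <- NA_integer_
  # absorption time into state 4
  t_abs <- ifelse(is.na(dest), Inf,
                  ifelse(dest == 4L, t_exit1,
                         t_exit1 + ifelse(dest == 2L,
                                          rexp0(n, q[, "2->4"]),
                                          rexp0(n, q[, "3->4"]))))
  cig_time <- ifelse(is.na(dest), Inf,
                     ifelse(dest == 3L, t_abs, t_exit1))
  ends_time <- ifelse(is.na(dest), Inf,
                      ifelse(dest == 2L, t_abs, t_exit1))
  cig_time[cig_time > survey_time] <- NA
  ends_time[ends_time > survey_time] <- NA
  alcohol_time[alcohol_time > survey_time] <- NA
  state_at <- function(tau) {
    use_state(!is.na(cig_time) & cig_time <= tau,
              !is.na(ends_time) & ends_time <= tau)
  }
  data.frame(subject_id = seq_len(n), sex = sex, grade = grade,
             paternal_edu3 = pedu3,
             alcohol_time = alcohol_time,
             cig_time = cig_time, ends_time = ends_time,
             baseline_time = baseline_time, survey_time = survey_time,
             state_baseline = state_at(baseline_time),
             state_survey = state_at(survey_time),
             stringsAsFactors = FALSE)
}

# months since grade-1 start -> questionnaire grade label
grade_label <- function(time_months) {
  ifelse(is.na(time_months), NA_character_,
         ifelse(time_months < 0, "before_elementary",
                as.character(pmin(12L, floor(time_months / 12) + 1L))))
}

#' Emit questionnaire records from simulated trajectories
#'
#' Converts initiation times to grade-at-first-use labels (grade g spans
#' months [12(g-1), 12g) since the start of grade 1; negative times report
#' "before_elementary"), draws past-30-day frequency bands conditional on
#' ever-use at survey time, maps the 3-level paternal-education truth back
#' to raw questionnaire responses, and injects MCAR missingness. A record
#' selected for initiation-grade missingness keeps its ever flag but blanks
#' the grade.
#'
#' @param traj Output of [simulate_trajectories()].
#' @param config The same [generator_config()].
#' @return A data.frame in the survey schema (see [build_cohort()]).
#' @export
emit_survey_records <- function(traj, config) {
  n <- nrow(traj)
  ever_cig <- !is.na(traj$cig_time)
  ever_ends <- !is.na(traj$ends_time)
  draw_band <- function(ever, probs) {
    out <- rep("none", n)
    k <- sum(ever)
    if (k > 0) out[ever] <- sample(FREQ_BANDS, k, replace = TRUE, prob = probs)
    out
  }
  raw_pedu <- function(level3) {
    switch(level3,
           college_or_higher = "college_or_higher",
           high_school_or_lower = sample(c("middle_or_lower", "high_school"), 1),
           unknown_NA = sample(c("dont_know", "father_absent"), 1))
  }
  rec <- data.frame(
    subject_id = traj$subject_id,
    sex = traj$sex,
    grade = traj$grade,
    ever_cig = ever_cig,
    cig_init_grade = grade_label(traj$cig_time),
    ever_ends = ever_ends,
    ends_init_grade = grade_label(traj$ends_time),
    alcohol_init_grade = grade_label(traj$alcohol_time),
    cig_30day_cat = draw_band(ever_cig, config$emission_probs$cig),
    ends_30day_cat = draw_band(ever_ends, config$emission_probs$ends),
    paternal_edu = vapply(traj$paternal_edu3, raw_pedu, character(1)),
    weight = 1,
    stringsAsFactors = FALSE)
  mr <- config$missingness_rates
  if (mr["cig_grade"] > 0)
    rec$cig_init_grade[ever_cig & stats::runif(n) < mr["cig_grade"]] <- NA
  if (mr["ends_grade"] > 0)
    rec$ends_init_grade[ever_ends & stats::runif(n) < mr["ends_grade"]] <- NA
  if (mr["paternal_edu"] > 0)
    rec$paternal_edu[stats::runif(n) < mr["paternal_edu"]] <- NA
  rownames(rec) <- NULL
  rec
}

#' Generate a complete synthetic survey dataset
#'
#' Deterministic given `config$seed`: seeds the RNG, simulates trajectories
#' and emits questionnaire records. The returned ground truth retains the
#' true states and generating configuration for parameter-recovery checks.
#'
#' @param config A [generator_config()].
#' @return List with `survey` (questionnaire records), `truth`
#'   (trajectories) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  traj <- simulate_trajectories(config)
  list(survey = emit_survey_records(traj, config), truth = traj,
       config = config)
}
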