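# shared fixtures and generators for the suite

# random valid progressive intensity matrix; rates span plausible scales
random_Q <- function(log_min = log(1e-4), log_max = log(0.3)) {
  q <- exp(stats::runif(5, log_min, log_max))
  intensity_matrix(q[1], q[2], q[3], q[4], q[5])
}

# the desk-scale generating rates used across simulation tests
DESK_RATES <- c("1->2" = 0.004, "1->3" = 0.0006, "1->4" = 0.0006,
                "2->4" = 0.025, "3->4" = 0.025)

# rates calibrated so q(3->4)/q(1->2) = 6.8, the recovery target ratio
RECOVERY_RATES <- c("1->2" = 0.004, "1->3" = 0.0006, "1->4" = 0.0006,
                    "2->4" = 0.025, "3->4" = 0.0272)

# tiny hand-built survey table covering all four end states
tiny_survey <- function() {
  data.frame(
    subject_id = 1:6,
    sex = c("male", "female", "male", "female", "male", "female"),
    grade = c(8L, 8L, 9L, 10L, 7L, 12L),
    ever_cig = c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE),
    cig_init_grade = c(NA, "7", "9", NA, "6", NA),
    ever_ends = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    ends_init_grade = c(NA, NA, "9", "8", NA, NA),
    alcohol_init_grade = c(NA, "8", "before_elementary", "10", NA, "5"),
    cig_30day_cat = c("none", "1-2", "everyday", "none", "none", "none"),
    ends_30day_cat = c("none", "none", "3-5", "1-2", "none", "none"),
    paternal_edu = c("college_or_higher", "high_school", "middle_or_lower",
                     "dont_know", "father_absent", "college_or_higher"),
    weight = 1,
    stringsAsFactors = FALSE)
}

# cohort from aggregated transition counts (single interval, no covariates)
cohort_from_counts <- function(counts, t = 4) {
  rows <- counts[counts$n > 0, , drop = FALSE]
  idx <- rep(seq_len(nrow(rows)), rows$n)
  data.frame(subject_id = seq_along(idx),
             baseline_state = rows$baseline[idx],
             end_state = rows$end[idx],
             interval_months = t,
             weight = 1)
}
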