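# Retrospective cohort construction from single-wave recall.
#
# Each respondent reports, at 4 months into the current school grade, the
# grade at which each product was first used. Initiation "at the previous
# grade or earlier" means the product was already an ever-use at the end of
# the previous grade (the baseline, end of February); initiation "at the
# current grade" happened during the 4-month follow-up. This turns one
# cross-sectional wave into a two-timepoint panel.

#' Apply the published complete-case exclusion rules
#'
#' Drops, in order: (a) ever-cigarette users missing the cigarette
#' initiation grade, (b) remaining ever-ENDS users missing the ENDS
#' initiation grade, (c) remaining records missing paternal education.
#' Sequential application counts each record under exactly one reason.
#'
#' @param records Survey data.frame (see [build_cohort()] for the schema).
#' @return List with `kept` (the retained records) and `log` (named integer
#'   vector of per-reason counts plus `total`).
#' @export
apply_exclusions <- function(records) {
  drop_a <- records$ever_cig & is.na(records$cig_init_grade)
  r1 <- records[!drop_a, , drop = FALSE]
  drop_b <- r1$ever_ends & is.na(r1$ends_init_grade)
  r2 <- r1[!drop_b, , drop = FALSE]
  drop_c <- is.na(r2$paternal_edu)
  kept <- r2[!drop_c, , drop = FALSE]
  log <- c(missing_cig_init_grade = sum(drop_a),
           missing_ends_init_grade = sum(drop_b),
           missing_paternal_edu = sum(drop_c))
  log <- c(log, total = sum(log))
  list(kept = kept, log = log)
}

#' Classify an initiation grade relative to the current grade
#'
#' A reported initiation grade equal to the current grade means the product
#' was first used during the follow-up ("current_grade"); a lower numeric
#' grade, or "before_elementary", means the respondent was already an ever
#' user at baseline ("previous_or_earlier"). Vectorised.
#'
#' @param init_grade Character vector: "before_elementary" or "1".."12"
#'   (numeric input is accepted).
#' @param current_grade Integer vector of current school grades (7..12).
#' @return Character vector in {"previous_or_earlier", "current_grade"}.
#' @details A numeric initiation grade greater than the current grade is
#'   inconsistent recall and raises an error naming the offending values.
#' @export
classify_initiation_timing <- function(init_grade, current_grade) {
  init_grade <- as.character(init_grade)
  stopifnot(length(init_grade) == length(current_grade))
  pre <- !is.na(init_grade) & init_grade == "before_elementary"
  g <- suppressWarnings(as.integer(init_grade))
  if (any(!pre & !is.na(init_grade) & is.na(g)))
    stop("classify_initiation_timing: unrecognised initiation grade value")
  bad <- !is.na(g) & g > current_grade
  if (any(bad))
    stop("classify_initiation_timing: initiation grade after current grade for ",
         sum(bad), " record(s) (inconsistent recall)")
  out <- rep(NA_character_, length(init_grade))
  out[pre | (!is.na(g) & g < current_grade)] <- "previous_or_earlier"
  out[!is.na(g) & g == current_grade] <- "current_grade"
  out
}

#' Derive baseline and end-of-follow-up use states
#'
#' The end state comes from the two ever-use flags; a product counts toward
#' the baseline state only if its initiation was at the previous grade or
#' earlier.
#'
#' @param records Survey data.frame that has passed [apply_exclusions()].
#' @return The input with integer columns `baseline_state` and `end_state`
#'   (codes 1..4) appended.
#' @export
derive_states <- function(records) {
  cig_timing <- rep(NA_character_, nrow(records))
  has_cg <- records$ever_cig & !is.na(records$cig_init_grade)
  cig_timing[has_cg] <- classify_initiation_timing(
    records$cig_init_grade[has_cg], records$grade[has_cg])
  ends_timing <- rep(NA_character_, nrow(records))
  has_eg <- records$ever_ends & !is.na(records$ends_init_grade)
  ends_timing[has_eg] <- classify_initiation_timing(
    records$ends_init_grade[has_eg], records$grade[has_eg])
  records$baseline_state <- use_state(
    !is.na(cig_timing) & cig_timing == "previous_or_earlier",
    !is.na(ends_timing) & ends_timing == "previous_or_earlier")
  records$end_state <- use_state(records$ever_cig, records$ever_ends)
  records
}

#' Derive model covariates from raw questionnaire responses
#'
#' Baseline grade is the current grade minus one; ever alcohol use at
#' baseline applies the same previous-grade-or-earlier rule as the tobacco
#' products; paternal education is recoded to three levels ("middle school
#' or lower" and "graduated high school" to high-school-or-lower,
#' "don't know" and father-absent to unknown/NA).
#'
#' @inheritParams derive_states
#' @return Input with columns `baseline_grade`, `ever_alcohol_baseline`,
#'   `paternal_edu_3level` appended.
#' @export
derive_covariates <- function(records) {
  records$baseline_grade <- records$grade - 1L
  alc <- rep(NA_character_, nrow(records))
  has_alc <- !is.na(records$alcohol_init_grade)
  alc[has_alc] <- classify_initiation_timing(
    records$alcohol_init_grade[has_alc], records$grade[has_alc])
  records$ever_alcohol_baseline <- !is.na(alc) & alc == "previous_or_earlier"
  recode <- c(middle_or_lower = "high_school_or_lower",
              high_school = "high_school_or_lower",
              college_or_higher = "college_or_higher",
              dont_know = "unknown_NA",
              father_absent = "unknown_NA")
  lev <- records$paternal_edu
  known <- !is.na(lev)
  if (any(known & !(lev %in% names(recode))))
    stop("derive_covariates: unrecognised paternal education value")
  out <- rep(NA_character_, length(lev))
  out[known] <- recode[lev[known]]
  records$paternal_edu_3level <- out
  records
}

#' Derive current (past-30-day) use flags
#'
#' A respondent is a current user of a product if the past-30-day frequency
#' is any nonzero band ("1-2" ... "everyday"). A nonzero band together with
#' a false ever flag is logically impossible; such records trigger a
#' data-consistency warning and the current flag is forced false.
#'
#' @inheritParams derive_states
#' @return Input with logical columns `current_cig` and `current_ends`.
#' @export
derive_current_use <- function(records) {
  nonzero <- function(x) !is.na(x) & x != "none"
  cur_cig <- nonzero(records$cig_30day_cat)
  cur_ends <- nonzero(records$ends_30day_cat)
  bad <- (cur_cig & !records$ever_cig) | (cur_ends & !records$ever_ends)
  if (any(bad)) {
    warning("derive_current_use: ", sum(bad),
            " record(s) report past-30-day use without ever use; ",
            "current flag forced false")
    cur_cig <- cur_cig & records$ever_cig
    cur_ends <- cur_ends & records$ever_ends
  }
  records$current_cig <- cur_cig
  records$current_ends <- cur_ends
  records
}

#' Build the retrospective cohort from raw survey records
#'
#' Composition of [apply_exclusions()], [derive_states()],
#' [derive_covariates()] and [derive_current_use()], with a fixed follow-up
#' interval of `interval_months` (default 4: end of February to the June
#' survey). The derived transition cross-table and the exclusion log are
#' attached as attributes.
#'
#' @param records Survey data.frame with columns `subject_id`, `sex`,
#'   `grade`, `ever_cig`, `cig_init_grade`, `ever_ends`, `ends_init_grade`,
#'   `alcohol_init_grade`, `cig_30day_cat`, `ends_30day_cat`,
#'   `paternal_edu`, `weight` (missing values as `NA`).
#' @param interval_months Panel interval length, default 4.
#' @return A cohort data.frame (one row per retained respondent) with
#'   attributes `transition_table` (4 x 4 count matrix) and
#'   `exclusion_log`.
#' @examples
#' cohort <- build_cohort(generate_table2_fixture())
#' attr(cohort, "transition_table")
#' @export
build_cohort <- function(records, interval_months = 4) {
  stopifnot(interval_months > 0)
  ex <- apply_exclusions(records)
  r <- derive_current_use(derive_covariates(derive_states(ex$kept)))
  reach <- transition_structure()$reachable
  bad <- !reach[cbind(r$baseline_state, r$end_state)]
  if (any(bad))
    stop("build_cohort: disallowed state transition for subject(s) ",
         paste(utils::head(r$subject_id[bad], 5), collapse = ", "))
  cohort <- data.frame(subject_id = r$subject_id,
                       baseline_state = r$baseline_state,
                       end_state = r$end_state,
                       interval_months = interval_months,
                       sex = r$sex,
                       baseline_grade = r$baseline_grade,
                       ever_alcohol_baseline = r$ever_alcohol_baseline,
                       paternal_edu_3level = r$paternal_edu_3level,
                       current_cig = r$current_cig,
                       current_ends = r$current_ends,
                       weight = if (is.null(r$weight)) 1 else r$weight,
                       stringsAsFactors = FALSE)
  attr(cohort, "transition_table") <- transition_table(cohort)
  attr(cohort, "exclusion_log") <- ex$log
  cohort
}

#' Transition cross-table of a cohort
#'
#' @param cohort Output of [build_cohort()].
#' @return 4 x 4 integer matrix of (baseline, end) counts.
#' @export
transition_table <- function(cohort) {
  tab <- table(factor(cohort$baseline_state, levels = 1:4),
               factor(cohort$end_state, levels = 1:4))
  m <- matrix(as.integer(tab), 4, 4,
              dimnames = list(baseline = 1:4, end = 1:4))
  m
}
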