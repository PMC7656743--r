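# Current-use prevalence by ever-use transition group.
#
# Movers (baseline state != end state) are cross-classified by their
# past-30-day use into mutually exclusive categories: currently using
# cigarettes only, ENDS only, or both. Default inference is unweighted
# with Wilson score intervals; a weighted mode takes user-supplied
# per-record weights and uses the effective sample size in the interval.

MOVER_GROUPS <- c("1->2", "1->3", "1->4", "2->4", "3->4")
PREV_CATEGORIES <- c("cig_only", "ends_only", "dual")

# Wilson score interval; accepts non-integer x/n for the weighted mode.
# Cross-checked against stats::prop.test(correct = FALSE) in the tests.
wilson_interval <- function(x, n, level = 0.95) {
  if (n <= 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Prevalence of current use by ever-use transition group
#'
#' For each of the five mover groups, cross-classifies current use into
#' cigarette-only, ENDS-only and dual, and reports counts, proportions and
#' 95% Wilson confidence intervals. With `weighted = TRUE`, proportions are
#' weighted (Horvitz-Thompson style) and intervals use the effective sample
#' size (sum w)^2 / sum w^2; with all weights equal the two modes agree
#' exactly.
#'
#' @param cohort Data.frame from [build_cohort()] (needs `baseline_state`,
#'   `end_state`, `current_cig`, `current_ends`, `weight`).
#' @param weighted Use the `weight` column, default `FALSE`.
#' @param level Confidence level, default 0.95.
#' @return Data.frame of class "prevalence_table", one row per (group,
#'   category): `group`, `n` (group size; effective size when weighted),
#'   `count`, `prop`, `lower`, `upper`. Empty groups are emitted with
#'   `n = 0` and `NA` proportions.
#' @examples
#' cohort <- build_cohort(generate_table2_fixture())
#' prevalence_by_transition(cohort)
#' @export
prevalence_by_transition <- function(cohort, weighted = FALSE, level = 0.95) {
  w <- if (weighted) cohort$weight else rep(1, nrow(cohort))
  lab <- paste0(cohort$baseline_state, "->", cohort$end_state)
  cat3 <- ifelse(cohort$current_cig & cohort$current_ends, "dual",
                 ifelse(cohort$current_cig, "cig_only",
                        ifelse(cohort$current_ends, "ends_only", "none")))
  rows <- list()
  for (g in MOVER_GROUPS) {
    in_g <- lab == g
    wsum <- sum(w[in_g])
    n_eff <- if (wsum > 0) wsum^2 / sum(w[in_g]^2) else 0
    for (cat in PREV_CATEGORIES) {
      cnt <- sum(w[in_g & cat3 == cat])
      if (wsum > 0) {
        p <- cnt / wsum
        ci <- wilson_interval(p * n_eff, n_eff, level)
      } else {
        p <- NA_real_; ci <- c(NA_real_, NA_real_)
      }
      rows[[length(rows) + 1]] <- data.frame(
        group = g, n = if (weighted) n_eff else wsum, count = cnt,
        prop = p, lower = ci[1], upper = ci[2])
    }
  }
  out <- do.call(rbind, rows)
  out$category <- rep(PREV_CATEGORIES, length(MOVER_GROUPS))
  out <- out[, c("group", "category", "n", "count", "prop", "lower", "upper")]
  rownames(out) <- NULL
  class(out) <- c("prevalence_table", "data.frame")
  attr(out, "level") <- level
  attr(out, "weighted") <- weighted
  out
}

#' Combined current-use proportion over several categories
#'
#' Pools the counts of the requested categories within one transition group
#' and recomputes the proportion with a single Wilson interval (not a sum
#' of intervals). Because the categories are mutually exclusive over the
#' same denominator, the point estimate equals the sum of the per-category
#' proportions.
#'
#' @param table A [prevalence_by_transition()] result.
#' @param group Transition group label, e.g. "2->4".
#' @param categories Subset of `c("cig_only", "ends_only", "dual")`.
#' @return List: `group`, `categories`, `n`, `count`, `prop`, `lower`,
#'   `upper`.
#' @examples
#' tab <- prevalence_by_transition(build_cohort(generate_table2_fixture()))
#' combined_proportion(tab, "2->4", c("cig_only", "dual"))
#' @export
combined_proportion <- function(table, group,
                                categories = c("cig_only", "dual")) {
  stopifnot(inherits(table, "prevalence_table"))
  if (!group %in% MOVER_GROUPS) stop("unknown transition group '", group, "'")
  if (!all(categories %in% PREV_CATEGORIES))
    stop("unknown category: ",
         paste(setdiff(categories, PREV_CATEGORIES), collapse = ", "))
  sub <- table[table$group == group & table$category %in% categories, ]
  n <- sub$n[1]
  cnt <- sum(sub$count)
  if (is.na(n) || n <= 0 || any(is.na(sub$prop)))
    return(list(group = group, categories = categories, n = n, count = cnt,
                prop = NA_real_, lower = NA_real_, upper = NA_real_))
  # disjoint categories over one denominator: pooled proportion is the sum
  p <- sum(sub$prop)
  ci <- wilson_interval(p * n, n, attr(table, "level"))
  list(group = group, categories = categories, n = n, count = cnt,
       prop = p, lower = ci[1], upper = ci[2])
}
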