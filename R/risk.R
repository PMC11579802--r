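#' Published age-specific cut-off scores for cerebral palsy risk
#'
#' Global Brief-HINE scores strictly below the age's threshold classify the
#' infant as at risk of cerebral palsy: below 22 at 3 months, below 25 at 6
#' months, and below 27 at 9 and 12 months.
#'
#' @return A tibble with columns `age_months` and `threshold`.
#' @examples
#' default_cutoffs()
#' @export
default_cutoffs <- function() {
  tibble(age_months = hine_ages(), threshold = c(22, 25, 27, 27))
}

#' Classify cerebral-palsy risk from the global score
#'
#' Strict-inequality rule: an exam is `at_risk` iff its global score is
#' strictly below the threshold for its age (a score of exactly 22 at 3
#' months is not at risk; 21.5 is). Half-point scores are compared
#' numerically.
#'
#' @param global_score Global Brief-HINE score(s) in 0--33.
#' @param age_months Assessment age(s); must appear in `cutoffs`.
#' @param cutoffs Cut-off table with columns `age_months` and `threshold`;
#'   defaults to the published values ([default_cutoffs()]), and accepts
#'   re-estimated thresholds from [liu_cutpoint()].
#' @return Character vector: `"at_risk"` or `"not_at_risk"`.
#' @examples
#' classify_risk(c(21.5, 22), c(3, 3))
#' @export
classify_risk <- function(global_score, age_months, cutoffs = default_cutoffs()) {
  if (!all(global_score >= 0 & global_score <= 33)) {
    abort("`global_score` must be in [0, 33]")
  }
  idx <- match(age_months, cutoffs$age_months)
  if (anyNA(idx)) {
    abort(sprintf(
      "no cut-off defined for age(s): %s",
      paste(unique(age_months[is.na(idx)]), collapse = ", ")
    ))
  }
  ifelse(global_score < cutoffs$threshold[idx], "at_risk", "not_at_risk")
}

#' Screen a table of exams
#'
#' One-stop screening report: scores every exam, counts warning signs,
#' applies the age-specific cut-off, and flags exams that call for the full
#' 26-item examination (more than one warning sign; in strict mode also any
#' exam with an item below the optimum for the age).
#'
#' @inheritParams validate_exams
#' @inheritParams classify_risk
#' @inheritParams is_warning_sign
#' @param strict Also refer exams with any item below the age-optimal score
#'   (off by default; the standard rule is `warning_count > 1`).
#' @return A tibble with one row per exam: `subject_id`, `age_months`,
#'   `global_score`, `asymmetry_count`, `warning_count`, `risk_class`, and
#'   `needs_full_exam`.
#' @examples
#' exams <- simulate_study(default_design(n_typical = 4, n_unilateral = 2,
#'   n_diplegia = 1, n_quadriplegia = 1, seed = 8))$exams
#' screen_exams(exams)
#' @export
screen_exams <- function(exams, cutoffs = default_cutoffs(),
                         rules = default_warning_rules(),
                         items = hine_items(), strict = FALSE) {
  scored <- score_exams(exams, items)
  profiles <- count_warning_signs(exams, rules = rules, items = items)
  scored |>
    left_join(
      profiles[, c("subject_id", "age_months", "warning_count", "suboptimal_count")],
      by = c("subject_id", "age_months")
    ) |>
    mutate(
      risk_class = classify_risk(.data$global_score, .data$age_months, cutoffs),
      needs_full_exam = needs_full_exam(.data$warning_count) |
        (strict & .data$suboptimal_count > 0)
    ) |>
    select(
      "subject_id", "age_months", "global_score", "asymmetry_count",
      "warning_count", "risk_class", "needs_full_exam"
    )
}
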