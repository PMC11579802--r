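#' Default warning-sign rules
#'
#' A warning sign is an item score lying outside the 90th centile of the
#' typical-outcome cohort for that age: column scores 0 and 1 for most
#' items. For the three age-related items (trunk posture, lateral tilting,
#' forward parachute) low scores are part of normal maturation at 3 and 6
#' months, so no score is flagged at those ages; scores 0 and 1 are flagged
#' from 9 months.
#'
#' @param items Item table, as returned by [hine_items()].
#' @return A tibble with one row per item x age and a `flagged_scores`
#'   list-column of flagged integer column scores (possibly empty).
#' @examples
#' default_warning_rules()
#' @export
default_warning_rules <- function(items = hine_items()) {
  tidyr::expand_grid(item_id = items$item_id, age_months = hine_ages()) |>
    left_join(items[, c("item_id", "age_related")], by = "item_id") |>
    mutate(flagged_scores = purrr::map2(
      .data$age_related, .data$age_months,
      function(age_rel, age) if (age_rel && age <= 6) integer() else 0:1
    )) |>
    select("item_id", "age_months", "flagged_scores")
}

lookup_flagged <- function(item_id, age_months, rules) {
  key <- paste(rules$item_id, rules$age_months)
  idx <- match(paste(item_id, age_months), key)
  if (anyNA(idx)) {
    abort(sprintf(
      "no warning rule for: %s",
      paste(unique(paste0(item_id, "@", age_months, "mo")[is.na(idx)]), collapse = ", ")
    ))
  }
  rules$flagged_scores[idx]
}

#' Is an item score a warning sign at a given age?
#'
#' Applies the warning-sign rule to an effective item score. Averaged
#' half-point scores arising from left/right asymmetry are flagged only when
#' the averaged score itself is at or below the highest flagged column score
#' (so with the default rules 0, 0.5, and 1 are warning signs but 1.5 is
#' not). Set `floor_half_scores = TRUE` to flag by the rounded-down column
#' instead (1.5 then counts as a 1).
#'
#' @param item_id Item identifier(s), see [hine_items()].
#' @param score Effective item score(s) in 0--3 (steps of 0.5).
#' @param age_months Assessment age(s): 3, 6, 9 or 12.
#' @param rules Warning-rule table, as [default_warning_rules()].
#' @param floor_half_scores Flag averaged half scores by their floor?
#' @return Logical vector.
#' @examples
#' is_warning_sign("trunk_posture", 1, 3)   # FALSE: exempt at 3 months
#' is_warning_sign("trunk_posture", 1, 12)  # TRUE
#' is_warning_sign("scarf_sign", 1.5, 9)    # FALSE under the default policy
#' @export
is_warning_sign <- function(item_id, score, age_months,
                            rules = default_warning_rules(),
                            floor_half_scores = FALSE) {
  if (!all(item_id %in% rules$item_id)) {
    abort(sprintf(
      "unknown item(s): %s",
      paste(setdiff(item_id, rules$item_id), collapse = ", ")
    ))
  }
  assert_ages(age_months)
  if (!all(score >= 0 & score <= 3)) {
    abort("`score` must be in [0, 3]")
  }
  flagged <- lookup_flagged(item_id, age_months, rules)
  eff <- if (floor_half_scores) floor(score) else score
  purrr::map2_lgl(eff, flagged, function(s, f) {
    length(f) > 0 && s <= max(f)
  })
}

#' Count warning signs per exam
#'
#' Applies [is_warning_sign()] to every item of every exam and returns one
#' warning profile per subject x age: the number of flagged items, which
#' items were flagged, and the number of items scoring below the optimum for
#' the age (used by the optional strict referral mode of [screen_exams()];
#' for age-related items at 3--6 months "optimal for age" means a column
#' score of 2 or more, otherwise 3).
#'
#' @inheritParams validate_exams
#' @inheritParams is_warning_sign
#' @return A tibble with columns `subject_id`, `age_months`,
#'   `warning_count`, `flagged_items` (list-column), and `suboptimal_count`.
#' @export
count_warning_signs <- function(exams, rules = default_warning_rules(),
                                items = hine_items(),
                                floor_half_scores = FALSE) {
  scores <- item_scores(exams, items) |>
    left_join(items[, c("item_id", "age_related")], by = "item_id")
  scores |>
    mutate(
      warning = is_warning_sign(
        .data$item_id, .data$score, .data$age_months,
        rules = rules, floor_half_scores = floor_half_scores
      ),
      optimal_floor = ifelse(.data$age_related & .data$age_months <= 6, 2, 3),
      suboptimal = .data$score < .data$optimal_floor
    ) |>
    group_by(.data$subject_id, .data$age_months) |>
    summarise(
      warning_count = sum(.data$warning),
      flagged_items = list(.data$item_id[.data$warning]),
      suboptimal_count = sum(.data$suboptimal),
      .groups = "drop"
    )
}

#' Does a warning profile call for the full 26-item examination?
#'
#' The screening rule refers an infant for a full neurological examination
#' when more than one warning sign is present (strictly more: a single
#' warning sign alone does not trigger referral).
#'
#' @param warning_count Integer vector of per-exam warning-sign counts.
#' @return Logical vector: `TRUE` where `warning_count > 1`.
#' @examples
#' needs_full_exam(c(0, 1, 2))
#' @export
needs_full_exam <- function(warning_count) {
  if (!all(warning_count >= 0)) {
    abort("`warning_count` must be non-negative")
  }
  warning_count > 1
}

#' Derive warning-sign rules from a typical-outcome cohort
#'
#' Recovers the warning-rule table empirically: for each item and age, a
#' column score `s` is flagged when the cumulative relative frequency of
#' scores at or below `s` in the typical-outcome cohort is under 10% --
#' i.e. the score lies outside the cohort's 90th centile. Applied to a
#' sufficiently large typical cohort this reproduces the fixed table of
#' [default_warning_rules()]: scores 0 and 1 flagged for the eight
#' non-age-related items at every age, and for the three age-related items
#' at 9 and 12 months only.
#'
#' @param typical_exams Exams from typical-outcome subjects only.
#' @inheritParams validate_exams
#' @param centile Flagging threshold on the cumulative relative frequency
#'   (default 0.10); ties at exactly the threshold are not flagged.
#' @return A tibble in the shape of [default_warning_rules()].
#' @export
derive_warning_scores <- function(typical_exams, items = hine_items(),
                                  centile = 0.10) {
  scores <- item_scores(typical_exams, items)
  if (nrow(scores) == 0) {
    abort("`typical_exams` must contain at least one exam")
  }
  scores |>
    group_by(.data$item_id, .data$age_months) |>
    summarise(
      flagged_scores = list({
        sc <- .data$score
        cum_freq <- vapply(0:3, function(s) mean(sc <= s), numeric(1))
        (0:3)[cum_freq < centile]
      }),
      .groups = "drop"
    ) |>
    arrange(match(.data$item_id, items$item_id), .data$age_months)
}

#' Export or import a warning-rule table as JSON
#'
#' Rules are stored as `item_id -> age -> flagged scores` so clinics can
#' version and override the defaults.
#'
#' @param rules Warning-rule table, as [default_warning_rules()].
#' @param path JSON file path.
#' @return `read_warning_rules()` returns the rule tibble;
#'   `write_warning_rules()` returns `rules` invisibly.
#' @name warning_rule_io
NULL

#' @rdname warning_rule_io
#' @export
write_warning_rules <- function(rules, path) {
  nested <- split(rules, rules$item_id) |>
    purrr::map(function(df) {
      stats::setNames(
        purrr::map(df$flagged_scores, as.integer),
        as.character(df$age_months)
      )
    })
  jsonlite::write_json(nested[unique(rules$item_id)], path, auto_unbox = FALSE)
  invisible(rules)
}

#' @rdname warning_rule_io
#' @export
read_warning_rules <- function(path) {
  nested <- jsonlite::read_json(path, simplifyVector = FALSE)
  purrr::imap(nested, function(ages, item) {
    tibble(
      item_id = item,
      age_months = as.integer(names(ages)),
      flagged_scores = purrr::map(ages, function(x) as.integer(unlist(x)) %||% integer())
    )
  }) |>
    bind_rows() |>
    arrange(.data$item_id, .data$age_months)
}
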