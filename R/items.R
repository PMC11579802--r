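#' The 11 Brief-HINE items
#'
#' Returns the item table for the 11-item short form of the Hammersmith
#' Infant Neurological Examination (Brief-HINE). Each item is scored on the
#' proforma in one of four optimality columns: 3 (findings seen in >75% of
#' typically developing infants), 2, 1, and 0 (findings seen in <10%).
#'
#' Three items -- trunk posture, lateral tilting, and the forward parachute
#' reaction -- have responses that mature with age: low scores on these are
#' unremarkable at 3 and 6 months (`age_related = TRUE`). Six limb and
#' postural-reaction items are recorded separately for the left and right
#' side (`paired = TRUE`); which items admit lateral recording is a package
#' convention and can be overridden by passing a modified item table to the
#' functions that accept one.
#'
#' @return A tibble with one row per item and columns `item_id`, `paired`,
#'   and `age_related`.
#' @examples
#' hine_items()
#' @export
hine_items <- function() {
  tibble(
    item_id = c(
      "visual_response", "trunk_posture", "movement_quantity",
      "movement_quality", "scarf_sign", "hip_adductors", "popliteal_angle",
      "pull_to_sit", "lateral_tilting", "forward_parachute", "tendon_reflexes"
    ),
    paired = c(
      FALSE, FALSE, FALSE,
      FALSE, TRUE, TRUE, TRUE,
      FALSE, TRUE, TRUE, TRUE
    ),
    age_related = c(
      FALSE, TRUE, FALSE,
      FALSE, FALSE, FALSE, FALSE,
      FALSE, TRUE, TRUE, FALSE
    )
  )
}

# expected exam-table columns for a given item table
exam_columns <- function(items = hine_items()) {
  item_cols <- unlist(purrr::map2(
    items$item_id, items$paired,
    function(id, p) if (p) paste0(id, c("_left", "_right")) else id
  ))
  c("subject_id", "age_months", item_cols)
}

#' Validate a table of Brief-HINE exams
#'
#' Checks that an exam table has the full column schema (one column per
#' unpaired item, `_left`/`_right` columns per paired item), that every
#' recorded column score is an integer in 0--3 with no missing values, that
#' ages are among the four assessment ages (3, 6, 9, 12 months), and that no
#' subject is examined twice at the same age. All problems are reported
#' together in a single error.
#'
#' @param exams A data frame of exams, one row per subject x age.
#' @param items Item table, as returned by [hine_items()].
#' @return `exams` (as a tibble), invisibly, if valid.
#' @export
validate_exams <- function(exams, items = hine_items()) {
  exams <- as_tibble(exams)
  problems <- character()

  missing_cols <- setdiff(exam_columns(items), names(exams))
  if (length(missing_cols) > 0) {
    problems <- c(problems, sprintf(
      "missing columns: %s", paste(missing_cols, collapse = ", ")
    ))
  } else {
    bad_age <- setdiff(unique(exams$age_months), hine_ages())
    if (length(bad_age) > 0) {
      problems <- c(problems, sprintf(
        "age_months must be in {3, 6, 9, 12}; found: %s",
        paste(bad_age, collapse = ", ")
      ))
    }
    score_cols <- setdiff(exam_columns(items), c("subject_id", "age_months"))
    for (col in score_cols) {
      v <- exams[[col]]
      if (anyNA(v) || !all(v %in% 0:3)) {
        problems <- c(problems, sprintf(
          "column score `%s` must be an integer in {0, 1, 2, 3} with no missing values",
          col
        ))
      }
    }
    dup <- exams |>
      count(.data$subject_id, .data$age_months) |>
      filter(.data$n > 1)
    if (nrow(dup) > 0) {
      problems <- c(problems, sprintf(
        "duplicate subject x age rows: %s",
        paste(paste0(dup$subject_id, "@", dup$age_months, "mo"), collapse = ", ")
      ))
    }
  }

  if (length(problems) > 0) {
    abort(c("Invalid exam table.", stats::setNames(problems, rep("x", length(problems)))))
  }
  invisible(exams)
}

#' Score one item, averaging left/right asymmetries
#'
#' Computes the per-item score from the recorded column score(s). For items
#' recorded on both sides, the item score is the shared column score when the
#' two sides agree and the arithmetic mean of the two column scores when they
#' differ (so asymmetric items can contribute half points, e.g. 2.5 for a
#' 3/2 split). Unpaired items score their single recorded column.
#'
#' @param left Integer column score(s) in 0--3 (the only side for unpaired
#'   items).
#' @param right Optional right-side column score(s); `NA` where the item is
#'   unpaired. Vectorised with `left`.
#' @return Numeric item score(s) in 0--3, in steps of 0.5.
#' @examples
#' score_item(3)        # unpaired item
#' score_item(3, 2)     # asymmetric: 2.5
#' score_item(1, 1)     # symmetric: 1
#' @export
score_item <- function(left, right = NULL) {
  if (!all(left %in% 0:3)) {
    abort("`left` column scores must be integers in {0, 1, 2, 3}")
  }
  if (is.null(right)) {
    return(as.numeric(left))
  }
  if (!all(right %in% 0:3 | is.na(right))) {
    abort("`right` column scores must be integers in {0, 1, 2, 3} (or NA when unpaired)")
  }
  ifelse(is.na(right), as.numeric(left), (left + right) / 2)
}

#' Per-item scores in long form
#'
#' Expands a wide exam table to one row per subject x age x item, applying
#' the asymmetry-averaging rule of [score_item()] and flagging asymmetric
#' responses (paired items whose left and right column scores differ).
#'
#' @inheritParams validate_exams
#' @return A tibble with columns `subject_id`, `age_months`, `item_id`,
#'   `score`, and `asymmetric`.
#' @export
item_scores <- function(exams, items = hine_items()) {
  exams <- validate_exams(exams, items)
  purrr::pmap(items, function(item_id, paired, age_related) {
    if (paired) {
      l <- exams[[paste0(item_id, "_left")]]
      r <- exams[[paste0(item_id, "_right")]]
    } else {
      l <- exams[[item_id]]
      r <- NA_integer_
    }
    tibble(
      subject_id = exams$subject_id,
      age_months = exams$age_months,
      item_id = item_id,
      score = score_item(l, if (paired) r else NULL),
      asymmetric = if (paired) l != r else rep(FALSE, nrow(exams))
    )
  }) |>
    bind_rows() |>
    arrange(.data$subject_id, .data$age_months)
}

#' Global Brief-HINE score and asymmetry count per exam
#'
#' Adds to an exam table the global score (sum of the 11 item scores, range
#' 0--33 in steps of 0.5) and the number of asymmetries (paired items whose
#' left and right column scores differ).
#'
#' @inheritParams validate_exams
#' @return The exam table with `global_score` and `asymmetry_count` columns
#'   appended.
#' @examples
#' exams <- simulate_study(default_design(n_typical = 5, n_unilateral = 2,
#'   n_diplegia = 2, n_quadriplegia = 2, seed = 1))$exams
#' score_exams(exams)[, c("subject_id", "age_months", "global_score")]
#' @export
score_exams <- function(exams, items = hine_items()) {
  exams <- validate_exams(exams, items)
  derived <- item_scores(exams, items) |>
    group_by(.data$subject_id, .data$age_months) |>
    summarise(
      global_score = sum(.data$score),
      asymmetry_count = sum(.data$asymmetric),
      .groups = "drop"
    )
  left_join(exams, derived, by = c("subject_id", "age_months"))
}

#' Read or write Brief-HINE exam and outcome tables
#'
#' Plain CSV interfaces for the two study tables. The exam CSV has one row
#' per subject x age with the column schema of [exam_columns]: `subject_id`,
#' `age_months`, one column per unpaired item and `_left`/`_right` columns
#' per paired item, integer cells 0--3. The outcome CSV has one row per
#' subject with `subject_id`, `outcome` (`typical` or `cp`) and `cp_subtype`
#' (`unilateral`, `bilateral_diplegia`, or `bilateral_quadriplegia`; empty
#' for typical outcomes). Both are validated on read and on write.
#'
#' @param path File path.
#' @param exams,outcomes Tables to write.
#' @param items Item table, as returned by [hine_items()].
#' @return `read_*` return validated tibbles; `write_*` return the input,
#'   invisibly.
#' @name exam_io
NULL

#' @rdname exam_io
#' @export
read_exams <- function(path, items = hine_items()) {
  exams <- readr::read_csv(path, show_col_types = FALSE)
  validate_exams(exams, items)
  exams
}

#' @rdname exam_io
#' @export
write_exams <- function(exams, path, items = hine_items()) {
  validate_exams(exams, items)
  readr::write_csv(exams[, exam_columns(items)], path)
  invisible(exams)
}

cp_subtypes <- function() c("unilateral", "bilateral_diplegia", "bilateral_quadriplegia")

#' Validate a table of 2-year outcome labels
#'
#' @param outcomes A data frame with columns `subject_id`, `outcome`
#'   (`typical`/`cp`), and `cp_subtype` (present iff `outcome == "cp"`).
#' @return `outcomes` (as a tibble), invisibly, if valid.
#' @export
validate_outcomes <- function(outcomes) {
  outcomes <- as_tibble(outcomes)
  problems <- character()
  missing_cols <- setdiff(c("subject_id", "outcome", "cp_subtype"), names(outcomes))
  if (length(missing_cols) > 0) {
    problems <- c(problems, sprintf(
      "missing columns: %s", paste(missing_cols, collapse = ", ")
    ))
  } else {
    if (!all(outcomes$outcome %in% c("typical", "cp"))) {
      problems <- c(problems, "`outcome` must be 'typical' or 'cp'")
    }
    bad_sub <- outcomes$outcome == "cp" & !(outcomes$cp_subtype %in% cp_subtypes())
    if (any(bad_sub)) {
      problems <- c(problems, sprintf(
        "CP subjects need `cp_subtype` in {%s}: %s",
        paste(cp_subtypes(), collapse = ", "),
        paste(outcomes$subject_id[bad_sub], collapse = ", ")
      ))
    }
    bad_typ <- outcomes$outcome == "typical" & !is.na(outcomes$cp_subtype)
    if (any(bad_typ)) {
      problems <- c(problems, sprintf(
        "`cp_subtype` must be empty for typical outcomes: %s",
        paste(outcomes$subject_id[bad_typ], collapse = ", ")
      ))
    }
    if (anyDuplicated(outcomes$subject_id)) {
      problems <- c(problems, "duplicate subject_id in outcome table")
    }
  }
  if (length(problems) > 0) {
    abort(c("Invalid outcome table.", stats::setNames(problems, rep("x", length(problems)))))
  }
  invisible(outcomes)
}

#' @rdname exam_io
#' @export
read_outcomes <- function(path) {
  outcomes <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      outcome = readr::col_character(),
      cp_subtype = readr::col_character()
    )
  )
  validate_outcomes(outcomes)
  outcomes
}

#' @rdname exam_io
#' @export
write_outcomes <- function(outcomes, path) {
  validate_outcomes(outcomes)
  readr::write_csv(outcomes[, c("subject_id", "outcome", "cp_subtype")], path)
  invisible(outcomes)
}
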