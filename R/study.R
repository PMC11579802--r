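#' Run the full screening study analysis
#'
#' Deterministic end-to-end pipeline over an exam table and its outcome
#' labels: validates and scores every exam, computes warning profiles, then
#' per assessment age estimates the Liu-method cut-point with its accuracy
#' metrics and stratified-bootstrap confidence intervals, and assembles the
#' study summary tables (group-wise score distributions, warning-sign
#' prevalence, and asymmetry profiles by CP subtype). Ages are analysed
#' independently, mirroring the per-age estimation of the published
#' cut-offs. Identical inputs and config give an identical report.
#'
#' @param exams Exam table (see [validate_exams()]) or path to an exam CSV.
#' @param outcomes Outcome table (see [validate_outcomes()]) or path to an
#'   outcome CSV.
#' @param config Named list overriding analysis settings: `boot_B`
#'   (bootstrap resamples, default 2000), `boot_seed` (default 1), `level`
#'   (default 0.95), `integer_grid` (restrict candidate thresholds to
#'   integers 0--34, default `FALSE`), `rules` (warning-rule table),
#'   `ks` (warning-count thresholds for prevalence, default 1:4).
#' @param items Item table, as returned by [hine_items()].
#' @return An object of class `bhine_study` with elements `score_summary`,
#'   `cutoffs`, `cutoff_ci`, `warning_prevalence`, `asymmetry_summary`,
#'   `screening`, `n`, and `config`.
#' @examples
#' study <- simulate_study(default_design(n_typical = 30, n_unilateral = 5,
#'   n_diplegia = 5, n_quadriplegia = 5, seed = 7))
#' report <- run_study(study$exams, study$outcomes, config = list(boot_B = 50))
#' report$cutoffs
#' @export
run_study <- function(exams, outcomes, config = list(), items = hine_items()) {
  if (is.character(exams)) exams <- read_exams(exams, items)
  if (is.character(outcomes)) outcomes <- read_outcomes(outcomes)
  cfg <- utils::modifyList(
    list(
      boot_B = 2000, boot_seed = 1, level = 0.95,
      integer_grid = FALSE, rules = NULL, ks = 1:4
    ),
    config
  )
  rules <- cfg$rules %||% default_warning_rules(items)

  scored <- score_exams(exams, items)
  labeled <- labeled_scores(scored, outcomes, items = items)
  message(sprintf(
    "run_study: %d exams, %d subjects (%d typical / %d CP)",
    nrow(scored), nrow(outcomes),
    sum(outcomes$outcome == "typical"), sum(outcomes$outcome == "cp")
  ))

  group_of <- function(outcome, subtype) {
    dplyr::case_when(
      outcome == "typical" ~ "typical",
      subtype == "unilateral" ~ "cp_unilateral",
      subtype == "bilateral_diplegia" ~ "cp_diplegia",
      subtype == "bilateral_quadriplegia" ~ "cp_quadriplegia"
    )
  }
  labeled <- labeled |>
    left_join(outcomes[, c("subject_id", "outcome")], by = "subject_id") |>
    mutate(group = group_of(.data$outcome, .data$cp_subtype))

  # Table-1-like score summaries: typical, pooled CP, and the subtypes
  summarise_scores <- function(d, label) {
    if (nrow(d) == 0) {
      return(tibble(
        age_months = integer(), group = character(), n = integer(),
        mean = numeric(), sd = numeric(), min = numeric(), max = numeric()
      ))
    }
    d |>
      group_by(.data$age_months) |>
      summarise(
        group = label, n = n(), mean = mean(.data$score),
        sd = stats::sd(.data$score), min = min(.data$score),
        max = max(.data$score), .groups = "drop"
      )
  }
  score_summary <- bind_rows(
    summarise_scores(filter(labeled, !.data$cp), "typical"),
    summarise_scores(filter(labeled, .data$cp), "cp"),
    labeled |>
      filter(.data$cp) |>
      group_by(.data$group) |>
      dplyr::group_map(~ summarise_scores(.x, .y$group)) |>
      bind_rows()
  ) |>
    select("group", "age_months", "n", "mean", "sd", "min", "max") |>
    arrange(.data$age_months, match(.data$group, c(
      "typical", "cp", "cp_unilateral", "cp_diplegia", "cp_quadriplegia"
    )))
  message(sprintf("run_study: score summaries for %d group x age cells", nrow(score_summary)))

  # Table-2-like per-age cut-point estimation
  estimable <- any(labeled$cp) && !all(labeled$cp)
  per_age <- purrr::map(hine_ages(), function(a) {
    d <- labeled[labeled$age_months == a, ]
    if (nrow(d) == 0 || !any(d$cp) || all(d$cp)) {
      return(list(
        cutoffs = tibble(
          age_months = a, threshold = NA_real_, sensitivity = NA_real_,
          specificity = NA_real_, ppv = NA_real_, npv = NA_real_,
          accuracy = NA_real_, auc = NA_real_, n_pos = sum(d$cp),
          n_neg = sum(!d$cp), degenerate = NA, note = "not estimable"
        ),
        ci = NULL
      ))
    }
    fit <- liu_cutpoint(d, integer_grid = cfg$integer_grid)
    ci <- bootstrap_ci(
      d,
      function(x) {
        m <- diag_metrics(confusion_at(x, fit$threshold))
        c(
          sensitivity = m$sensitivity, specificity = m$specificity,
          ppv = m$ppv, npv = m$npv, accuracy = m$accuracy, auc = auc_mw(x)
        )
      },
      B = cfg$boot_B, level = cfg$level, seed = cfg$boot_seed + a
    )
    list(
      cutoffs = bind_cols(tibble(age_months = a), glance(fit), tibble(note = "")),
      ci = mutate(ci, age_months = a, .before = 1)
    )
  })
  cutoffs <- bind_rows(purrr::map(per_age, "cutoffs"))
  cutoff_ci <- bind_rows(purrr::map(per_age, "ci"))
  message(sprintf(
    "run_study: cut-points estimated at %d of %d ages",
    sum(cutoffs$note == ""), length(hine_ages())
  ))

  # warning-sign prevalence and asymmetry profiles
  profiles <- count_warning_signs(exams, rules = rules, items = items) |>
    left_join(
      labeled[, c("subject_id", "age_months", "group", "cp")],
      by = c("subject_id", "age_months")
    )
  prevalence <- warning_prevalence(
    profiles |> mutate(group = ifelse(.data$cp, "cp", "typical")),
    ks = cfg$ks
  ) |>
    bind_rows(warning_prevalence(filter(profiles, .data$cp), ks = cfg$ks))
  asymmetry_summary <- scored |>
    left_join(labeled[, c("subject_id", "age_months", "group")],
      by = c("subject_id", "age_months")
    ) |>
    group_by(.data$group, .data$age_months) |>
    summarise(
      median = stats::median(.data$asymmetry_count),
      min = min(.data$asymmetry_count), max = max(.data$asymmetry_count),
      .groups = "drop"
    )

  screening_cutoffs <- if (estimable && all(cutoffs$note == "")) {
    cutoffs[, c("age_months", "threshold")]
  } else {
    default_cutoffs()
  }
  screening <- screen_exams(exams,
    cutoffs = screening_cutoffs, rules = rules, items = items
  )

  structure(
    list(
      score_summary = score_summary,
      cutoffs = cutoffs,
      cutoff_ci = cutoff_ci,
      warning_prevalence = prevalence,
      asymmetry_summary = asymmetry_summary,
      screening = screening,
      n = list(
        subjects = nrow(outcomes), exams = nrow(exams),
        typical = sum(outcomes$outcome == "typical"),
        cp = sum(outcomes$outcome == "cp")
      ),
      config = cfg
    ),
    class = "bhine_study"
  )
}

#' Warning-sign prevalence by group and age
#'
#' Percentage of exams with strictly more than `k` warning signs, for each
#' count threshold `k`, per group and assessment age (the tail percentages
#' reported per cohort, e.g. "56% had more than three warning signs at 3
#' months").
#'
#' @param profiles Warning profiles with a `group` column (see
#'   [count_warning_signs()]).
#' @param ks Integer count thresholds (default `1:4`).
#' @return A tibble with `group`, `age_months`, `k`, `n`, and `pct`
#'   (percentage in 0--100, non-increasing in `k` within group x age).
#' @examples
#' profiles <- tibble::tibble(group = "typical", age_months = 3,
#'                            warning_count = c(0, 2, 2, 5))
#' warning_prevalence(profiles)
#' @export
warning_prevalence <- function(profiles, ks = 1:4) {
  if (!"group" %in% names(profiles)) {
    abort("`profiles` needs a `group` column")
  }
  tidyr::expand_grid(
    distinct(profiles[, c("group", "age_months")]),
    k = ks
  ) |>
    left_join(profiles, by = c("group", "age_months"),
      relationship = "many-to-many"
    ) |>
    group_by(.data$group, .data$age_months, .data$k) |>
    summarise(
      n = n(),
      pct = 100 * mean(.data$warning_count > .data$k[1]),
      .groups = "drop"
    )
}

#' @export
print.bhine_study <- function(x, ...) {
  cat(sprintf(
    "Brief-HINE study report: %d subjects (%d typical, %d CP), %d exams\n\n",
    x$n$subjects, x$n$typical, x$n$cp, x$n$exams
  ))
  cat("Per-age Liu cut-points:\n")
  print(as.data.frame(x$cutoffs[, c(
    "age_months", "threshold", "sensitivity", "specificity",
    "ppv", "npv", "accuracy", "auc"
  )]), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Tidy a study report
#'
#' @param x A `bhine_study` object.
#' @param ... Unused.
#' @return `tidy()`: the per-age cut-point table. `glance()`: a one-row
#'   study summary.
#' @export
tidy.bhine_study <- function(x, ...) x$cutoffs

#' @rdname tidy.bhine_study
#' @export
glance.bhine_study <- function(x, ...) {
  tibble(
    n_subjects = x$n$subjects, n_exams = x$n$exams,
    n_typical = x$n$typical, n_cp = x$n$cp,
    min_auc = min(x$cutoffs$auc), max_auc = max(x$cutoffs$auc)
  )
}

## --- report rendering --------------------------------------------------------

fmt2 <- function(x) {
  ifelse(is.na(x), "NA", sub("\\.?0+$", "", sprintf("%.2f", round_half_up(x, 2))))
}

# "mean (sd; min-max)" in the style of the published score table
fmt_summary <- function(mean, sd, min, max) {
  sprintf("%s (%s; %s-%s)", fmt2(mean), fmt2(sd), fmt2(min), fmt2(max))
}

#' Render a study report to files
#'
#' Writes the report tables as CSV (one file per table), a single JSON
#' document, and/or a human-readable markdown summary with the customary
#' compact strings (scores as "mean (SD; range)", accuracy as
#' "sens-spec" / "PPV-NPV-ACC" pairs, 2 decimals, halves rounded up).
#'
#' @param report A `bhine_study` object from [run_study()].
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("csv", "json", "md")`.
#' @return The paths of the files written, invisibly.
#' @export
render_report <- function(report, dir, formats = c("csv", "json", "md")) {
  unknown <- setdiff(formats, c("csv", "json", "md"))
  if (length(unknown) > 0) {
    abort(sprintf("unknown format(s): %s", paste(unknown, collapse = ", ")))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- list(
    score_summary = report$score_summary,
    cutoffs = report$cutoffs,
    cutoff_ci = report$cutoff_ci,
    warning_prevalence = report$warning_prevalence,
    asymmetry_summary = report$asymmetry_summary,
    screening = report$screening
  )
  written <- character()
  if ("csv" %in% formats) {
    for (nm in names(tables)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      readr::write_csv(tables[[nm]], p)
      written <- c(written, p)
    }
  }
  if ("json" %in% formats) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(c(tables, list(n = report$n)), p,
      auto_unbox = TRUE, digits = NA, na = "null"
    )
    written <- c(written, p)
  }
  if ("md" %in% formats) {
    p <- file.path(dir, "report.md")
    writeLines(render_markdown(report), p)
    written <- c(written, p)
  }
  invisible(written)
}

render_markdown <- function(report) {
  md_table <- function(df) {
    cells <- vapply(df, function(col) as.character(col), character(nrow(df)))
    cells <- matrix(cells, nrow = nrow(df))
    c(
      paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    )
  }
  scores_wide <- report$score_summary |>
    mutate(cell = fmt_summary(.data$mean, .data$sd, .data$min, .data$max)) |>
    select("group", "age_months", "cell") |>
    tidyr::pivot_wider(names_from = "age_months", values_from = "cell",
      names_prefix = "m"
    )
  cut_tbl <- report$cutoffs |>
    mutate(
      `sens-spec` = paste0(fmt2(.data$sensitivity), "-", fmt2(.data$specificity)),
      `ppv-npv-acc` = paste0(
        fmt2(.data$ppv), "-", fmt2(.data$npv), "-", fmt2(.data$accuracy)
      ),
      auc = fmt2(.data$auc)
    ) |>
    select("age_months", "threshold", "sens-spec", "ppv-npv-acc", "auc")
  prev_tbl <- report$warning_prevalence |>
    mutate(pct = fmt2(.data$pct)) |>
    tidyr::pivot_wider(names_from = "k", values_from = "pct", names_prefix = ">")
  asym_tbl <- report$asymmetry_summary |>
    mutate(cell = sprintf("%s (%s-%s)", fmt2(.data$median), fmt2(.data$min), fmt2(.data$max))) |>
    select("group", "age_months", "cell") |>
    tidyr::pivot_wider(names_from = "age_months", values_from = "cell",
      names_prefix = "m"
    )
  c(
    "# Brief-HINE study report",
    "",
    sprintf(
      "%d subjects (%d typical outcome, %d CP), %d exams.",
      report$n$subjects, report$n$typical, report$n$cp, report$n$exams
    ),
    "",
    "## Global scores by group and age: mean (SD; range)",
    "",
    md_table(scores_wide),
    "",
    "## Cut-off scores by age at assessment",
    "",
    md_table(cut_tbl),
    "",
    "## Warning signs: % of exams with more than k signs",
    "",
    md_table(prev_tbl),
    "",
    "## Asymmetries per exam: median (range)",
    "",
    md_table(asym_tbl)
  )
}
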