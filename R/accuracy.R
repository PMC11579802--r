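#' Build a labeled-scores table for diagnostic-accuracy analysis
#'
#' Joins scored exams to 2-year outcome labels and returns, per assessment
#' age, the canonical table the accuracy functions operate on: one row per
#' exam with the global score and a logical `cp` label (CP = positive class).
#' Throughout the package the positive call is a LOW score: an exam is
#' called positive (at risk) when `score < threshold`.
#'
#' @param exams Exam table (scored or not; scored on the fly if needed).
#' @param outcomes Outcome table, see [validate_outcomes()].
#' @param age_months Optional single age to restrict to.
#' @param items Item table, as returned by [hine_items()].
#' @return A tibble with columns `subject_id`, `age_months`, `score`, `cp`,
#'   and `cp_subtype`.
#' @export
labeled_scores <- function(exams, outcomes, age_months = NULL,
                           items = hine_items()) {
  validate_outcomes(outcomes)
  if (!"global_score" %in% names(exams)) {
    exams <- score_exams(exams, items)
  }
  unlabeled <- setdiff(exams$subject_id, outcomes$subject_id)
  if (length(unlabeled) > 0) {
    abort(sprintf(
      "no outcome label for subject(s): %s",
      paste(utils::head(unlabeled, 10), collapse = ", ")
    ))
  }
  out <- exams |>
    left_join(outcomes, by = "subject_id") |>
    mutate(score = .data$global_score, cp = .data$outcome == "cp") |>
    select("subject_id", "age_months", "score", "cp", "cp_subtype")
  if (!is.null(age_months)) {
    out <- out[out$age_months == age_months, ]
  }
  out
}

assert_two_classes <- function(data) {
  if (!all(c("score", "cp") %in% names(data))) {
    abort("labeled scores need `score` and `cp` columns (see `labeled_scores()`)")
  }
  if (!any(data$cp) || all(data$cp)) {
    abort("both classes (CP and typical) must be present")
  }
  invisible(data)
}

#' Confusion counts at a threshold
#'
#' Cross-tabulates the low-score-positive rule `score < threshold` against
#' the CP labels.
#'
#' @param data Labeled scores, see [labeled_scores()].
#' @param threshold Decision threshold.
#' @return A one-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @examples
#' d <- tibble::tibble(score = c(10, 12, 25, 26), cp = c(TRUE, TRUE, FALSE, FALSE))
#' confusion_at(d, 22)
#' @export
confusion_at <- function(data, threshold) {
  positive <- data$score < threshold
  tibble(
    tp = sum(positive & data$cp),
    fp = sum(positive & !data$cp),
    tn = sum(!positive & !data$cp),
    fn = sum(!positive & data$cp)
  )
}

#' Diagnostic metrics from confusion counts
#'
#' Sensitivity, specificity, positive and negative predictive values, and
#' overall accuracy. Metrics with a zero denominator are returned as `NA`
#' (undefined), never as 0.
#'
#' @param counts A one-row data frame (or list) with `tp`, `fp`, `tn`, `fn`.
#' @return A one-row tibble with `sensitivity`, `specificity`, `ppv`,
#'   `npv`, and `accuracy`.
#' @examples
#' diag_metrics(list(tp = 72, fp = 18, tn = 210, fn = 10))
#' @export
diag_metrics <- function(counts) {
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  with(counts, {
    if (any(c(tp, fp, tn, fn) < 0)) abort("confusion counts must be non-negative")
    tibble(
      sensitivity = safe_div(tp, tp + fn),
      specificity = safe_div(tn, tn + fp),
      ppv = safe_div(tp, tp + fp),
      npv = safe_div(tn, tn + fn),
      accuracy = safe_div(tp + tn, tp + fp + tn + fn)
    )
  })
}

#' Reconstruct counts and predictive values from published rates
#'
#' Given a published sensitivity/specificity pair and the cohort sizes,
#' rebuilds the integer confusion counts (rounding half up) and recomputes
#' all metrics -- the arithmetic that links a screening study's reported
#' sensitivity/specificity to its reported PPV, NPV, and accuracy at the
#' study's prevalence.
#'
#' @param sensitivity,specificity Rates in 0--1.
#' @param n_pos,n_neg Positive (CP) and negative (typical) cohort sizes.
#' @return A one-row tibble with the counts and all five metrics.
#' @examples
#' metrics_from_rates(0.88, 0.92, n_pos = 82, n_neg = 228)
#' @export
metrics_from_rates <- function(sensitivity, specificity, n_pos, n_neg) {
  stopifnot(
    sensitivity >= 0, sensitivity <= 1, specificity >= 0, specificity <= 1,
    n_pos > 0, n_neg > 0
  )
  tp <- round_half_up(sensitivity * n_pos)
  tn <- round_half_up(specificity * n_neg)
  counts <- tibble(tp = tp, fp = n_neg - tn, tn = tn, fn = n_pos - tp)
  dplyr::bind_cols(counts, diag_metrics(counts))
}

# candidate thresholds: distinct observed scores plus one value above the
# maximum (so the all-positive corner is reachable), or the integer grid
candidate_thresholds <- function(scores, integer_grid = FALSE) {
  if (integer_grid) 0:34 else sort(unique(c(scores, max(scores) + 1)))
}

#' Empirical ROC points
#'
#' Sweeps the low-score-positive rule `score < threshold` over all candidate
#' thresholds (distinct observed scores plus one value above the maximum)
#' and returns one operating point per threshold. Sensitivity and the
#' false-positive rate are both non-decreasing in the threshold; the sweep
#' always contains the (0, 0) and (1, 1) corners.
#'
#' @inheritParams confusion_at
#' @param integer_grid Restrict candidate thresholds to the integers 0--34.
#' @return A tibble with `threshold`, `sensitivity`, `specificity`, `fpr`,
#'   ordered by threshold.
#' @export
roc_points <- function(data, integer_grid = FALSE) {
  assert_two_classes(data)
  thresholds <- candidate_thresholds(data$score, integer_grid)
  pos <- data$score[data$cp]
  neg <- data$score[!data$cp]
  tibble(
    threshold = thresholds,
    sensitivity = vapply(thresholds, function(c) mean(pos < c), numeric(1)),
    specificity = vapply(thresholds, function(c) mean(neg >= c), numeric(1))
  ) |>
    mutate(fpr = 1 - .data$specificity)
}

#' Area under the ROC curve (Mann--Whitney estimator)
#'
#' The probability that a randomly chosen typical-outcome infant scores
#' higher than a randomly chosen CP infant, counting ties as one half --
#' computed rank-based in O(n log n). Equals the trapezoidal area under the
#' empirical ROC of [roc_points()].
#'
#' @inheritParams confusion_at
#' @return AUC in 0--1.
#' @export
auc_mw <- function(data) {
  assert_two_classes(data)
  r <- rank(data$score, ties.method = "average")
  n_neg <- sum(!data$cp)
  n_pos <- sum(data$cp)
  (sum(r[!data$cp]) - n_neg * (n_neg + 1) / 2) / (n_neg * n_pos)
}

#' Liu-method optimal cut-point
#'
#' Estimates the decision threshold maximizing the product of sensitivity
#' and specificity (the Liu criterion) on the empirical ROC, under the
#' low-score-positive rule `score < threshold`. Candidate thresholds are the
#' distinct observed scores plus one value above the maximum; ties in the
#' product are broken toward the smallest (most specific) threshold. When
#' every candidate has a zero product (e.g. all scores identical) the
#' smallest candidate is returned with `degenerate = TRUE`.
#'
#' @inheritParams roc_points
#' @return An object of class `liu_cutpoint`: the chosen `threshold`, the
#'   metrics at that threshold, the Mann--Whitney `auc`, class sizes, a
#'   `degenerate` flag, and the full candidate sweep. Use [tidy()] /
#'   [glance()] for tibble views and [ggplot2::autoplot()] for the ROC plot.
#' @examples
#' d <- tibble::tibble(
#'   score = c(10, 12, 25, 26, 27),
#'   cp = c(TRUE, TRUE, FALSE, FALSE, FALSE)
#' )
#' liu_cutpoint(d)
#' @export
liu_cutpoint <- function(data, integer_grid = FALSE) {
  assert_two_classes(data)
  sweep <- roc_points(data, integer_grid) |>
    mutate(product = .data$sensitivity * .data$specificity)
  best <- which.max(sweep$product) # first index on ties: smallest threshold
  threshold <- sweep$threshold[best]
  counts <- confusion_at(data, threshold)
  structure(
    c(
      list(threshold = threshold),
      as.list(diag_metrics(counts)),
      list(
        product = sweep$product[best],
        auc = auc_mw(data),
        n_pos = sum(data$cp),
        n_neg = sum(!data$cp),
        degenerate = max(sweep$product) == 0,
        counts = counts,
        sweep = sweep,
        integer_grid = integer_grid
      )
    ),
    class = "liu_cutpoint"
  )
}

#' @export
print.liu_cutpoint <- function(x, ...) {
  cat("Liu-method cut-point (positive call: score < threshold)\n")
  cat(sprintf(
    "  threshold %s%s  (n_pos = %d, n_neg = %d)\n",
    format(x$threshold), if (x$degenerate) " [degenerate]" else "",
    x$n_pos, x$n_neg
  ))
  cat(sprintf(
    "  sens %.2f  spec %.2f  ppv %.2f  npv %.2f  acc %.2f  auc %.3f\n",
    x$sensitivity, x$specificity, x$ppv, x$npv, x$accuracy, x$auc
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Liu cut-point fit
#'
#' @param x A `liu_cutpoint` object.
#' @param ... Unused.
#' @return `tidy()`: one row per candidate threshold with sensitivity,
#'   specificity, and their product. `glance()`: a one-row summary with the
#'   chosen threshold and all metrics.
#' @export
tidy.liu_cutpoint <- function(x, ...) {
  x$sweep
}

#' @rdname tidy.liu_cutpoint
#' @export
glance.liu_cutpoint <- function(x, ...) {
  tibble(
    threshold = x$threshold,
    sensitivity = x$sensitivity,
    specificity = x$specificity,
    ppv = x$ppv,
    npv = x$npv,
    accuracy = x$accuracy,
    auc = x$auc,
    n_pos = x$n_pos,
    n_neg = x$n_neg,
    degenerate = x$degenerate
  )
}

#' Stratified bootstrap confidence intervals
#'
#' Percentile bootstrap with resampling stratified by class (CP and typical
#' subjects resampled separately, so every resample keeps both classes).
#' The statistic may return a named vector to get intervals for several
#' metrics from one set of resamples.
#'
#' @inheritParams confusion_at
#' @param statistic Function of a labeled-scores tibble returning a numeric
#'   scalar or named vector.
#' @param B Number of bootstrap resamples (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; required for reproducibility, applied locally
#'   without disturbing the caller's RNG state.
#' @return A tibble with columns `term`, `estimate`, `conf_low`,
#'   `conf_high`.
#' @examples
#' d <- tibble::tibble(score = c(10, 14, 20, 24, 26, 28, 30),
#'                     cp = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
#' bootstrap_ci(d, auc_mw, B = 200, seed = 42)
#' @export
bootstrap_ci <- function(data, statistic, B = 2000, level = 0.95, seed = NULL) {
  assert_two_classes(data)
  stopifnot(B >= 1, level > 0, level < 1)
  est <- statistic(data)
  idx_pos <- which(data$cp)
  idx_neg <- which(!data$cp)
  draw <- function() {
    i <- c(sample(idx_pos, replace = TRUE), sample(idx_neg, replace = TRUE))
    statistic(data[i, , drop = FALSE])
  }
  run <- function() {
    vapply(seq_len(B), function(b) draw(), numeric(length(est)))
  }
  boots <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  boots <- matrix(boots, nrow = length(est))
  alpha <- (1 - level) / 2
  tibble(
    term = names(est) %||% rep("statistic", length(est)),
    estimate = unname(est),
    conf_low = apply(boots, 1, quantile, probs = alpha, na.rm = TRUE),
    conf_high = apply(boots, 1, quantile, probs = 1 - alpha, na.rm = TRUE)
  )
}
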