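# Build a one-row exam with every item at `fill`, overridable per column,
# e.g. make_exam(age = 3, scarf_sign_left = 3, scarf_sign_right = 2).
make_exam <- function(subject_id = "S1", age = 12, fill = 3, ...) {
  cols <- setdiff(briefhine:::exam_columns(), c("subject_id", "age_months"))
  row <- as.list(stats::setNames(rep(as.integer(fill), length(cols)), cols))
  over <- list(...)
  stopifnot(all(names(over) %in% cols))
  row[names(over)] <- lapply(over, as.integer)
  tibble::as_tibble(c(list(subject_id = subject_id, age_months = age), row))
}

# Random valid exam table: uniform independent column scores.
random_exams <- function(n, ages = c(3L, 6L, 9L, 12L)) {
  cols <- setdiff(briefhine:::exam_columns(), c("subject_id", "age_months"))
  out <- tibble::tibble(
    subject_id = sprintf("R%03d", seq_len(n)),
    age_months = sample(ages, n, replace = TRUE)
  )
  for (col in cols) out[[col]] <- sample(0:3, n, replace = TRUE)
  out
}

# Independent scoring oracle: per-item score from raw columns, by brute force.
oracle_global_score <- function(exam_row) {
  items <- hine_items()
  total <- 0
  for (j in seq_len(nrow(items))) {
    id <- items$item_id[j]
    if (items$paired[j]) {
      l <- exam_row[[paste0(id, "_left")]]
      r <- exam_row[[paste0(id, "_right")]]
      total <- total + if (l == r) l else (l + r) / 2
    } else {
      total <- total + exam_row[[id]]
    }
  }
  total
}

# Random labeled-scores dataset on the 0.5 score grid (ties likely).
random_labeled <- function(n_pos, n_neg, lo = 0, hi = 33) {
  grid <- seq(lo, hi, by = 0.5)
  tibble::tibble(
    score = sample(grid, n_pos + n_neg, replace = TRUE),
    cp = rep(c(TRUE, FALSE), c(n_pos, n_neg))
  )
}

# Exhaustive Liu sweep oracle: argmax of sens * spec over the candidate set,
# smallest threshold on ties.
oracle_liu <- function(data, integer_grid = FALSE) {
  cand <- if (integer_grid) 0:34 else sort(unique(c(data$score, max(data$score) + 1)))
  prod <- vapply(cand, function(c) {
    mean(data$score[data$cp] < c) * mean(data$score[!data$cp] >= c)
  }, numeric(1))
  cand[which(prod == max(prod))[1]]
}

# O(n^2) pairwise Mann-Whitney oracle.
oracle_auc <- function(data) {
  pos <- data$score[data$cp]
  neg <- data$score[!data$cp]
  cmp <- outer(neg, pos, ">") + 0.5 * outer(neg, pos, "==")
  mean(cmp)
}

trapezoid_area <- function(roc) {
  x <- roc$fpr
  y <- roc$sensitivity
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
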