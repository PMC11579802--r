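#' Published group-wise global-score distributions
#'
#' Per-group, per-age parameters (mean, SD, range) of the global Brief-HINE
#' score used to calibrate the synthetic cohort generator: the
#' typical-outcome cohort and the three cerebral-palsy subtypes at 3, 6, 9,
#' and 12 months. SDs are published only for the typical cohort; subtype
#' SDs default to range/4 (the usual normal-range heuristic).
#'
#' @return A tibble with columns `group`, `age_months`, `mean`, `sd`,
#'   `min`, `max`.
#' @examples
#' default_score_specs()
#' @export
default_score_specs <- function() {
  spec <- function(group, age, mean, sd, min, max) {
    tibble(
      group = group, age_months = age, mean = mean,
      sd = sd %||% ((max - min) / 4), min = min, max = max
    )
  }
  bind_rows(
    spec("typical", 3L, 23, 2.2, 18, 30),
    spec("typical", 6L, 28, 1.9, 22, 32),
    spec("typical", 9L, 30, 2.2, 20, 33),
    spec("typical", 12L, 31, 1.6, 27, 33),
    spec("cp_unilateral", 3L, 16.5, NULL, 10, 24),
    spec("cp_unilateral", 6L, 21, NULL, 13, 30),
    spec("cp_unilateral", 9L, 25.5, NULL, 18, 28),
    spec("cp_unilateral", 12L, 25, NULL, 19, 30),
    spec("cp_diplegia", 3L, 14.5, NULL, 6, 23),
    spec("cp_diplegia", 6L, 20, NULL, 11, 26),
    spec("cp_diplegia", 9L, 22, NULL, 14, 27),
    spec("cp_diplegia", 12L, 24.5, NULL, 21, 33),
    spec("cp_quadriplegia", 3L, 13.5, NULL, 3, 18),
    spec("cp_quadriplegia", 6L, 12.5, NULL, 6, 21),
    spec("cp_quadriplegia", 9L, 11, NULL, 6, 21),
    spec("cp_quadriplegia", 12L, 12.5, NULL, 10, 21)
  )
}

#' Published per-exam asymmetry-count profiles for the CP subtypes
#'
#' Median and range of the number of asymmetric items per exam, by subtype
#' and age: unilateral CP shows a median of 1 asymmetry at 3--6 months and 2
#' at 9--12 months (range 0--6); both bilateral subtypes have median 0 at
#' all ages (range 0--2 for diplegia, 0--3 for quadriplegia). The typical
#' cohort is handled separately in [simulate_study()]: a single-asymmetry
#' exam at frequency 10/228, never more than one.
#'
#' @return A tibble with columns `group`, `age_months`, `median`, `min`,
#'   `max`.
#' @export
default_asymmetry_specs <- function() {
  tidyr::expand_grid(
    group = c("cp_unilateral", "cp_diplegia", "cp_quadriplegia"),
    age_months = hine_ages()
  ) |>
    mutate(
      median = ifelse(.data$group == "cp_unilateral",
        ifelse(.data$age_months <= 6, 1L, 2L), 0L
      ),
      min = 0L,
      max = dplyr::case_when(
        .data$group == "cp_unilateral" ~ 6L,
        .data$group == "cp_diplegia" ~ 2L,
        TRUE ~ 3L
      )
    )
}

#' Study design for the synthetic cohort
#'
#' Defaults reproduce the study composition: 228 typical-outcome infants
#' and 82 who developed CP (40 unilateral, 17 bilateral diplegia, 25
#' bilateral quadriplegia), each examined at 3, 6, 9, and 12 months.
#' `rho` is the pairwise correlation of a subject's latent score quantile
#' across ages (Gaussian copula): at `rho = 1` a subject keeps the same
#' within-group quantile at every age.
#'
#' @param n_typical,n_unilateral,n_diplegia,n_quadriplegia Group sizes.
#' @param rho Between-age latent correlation in `[0, 1]` (default 0.8).
#' @param seed Integer seed for the whole simulation.
#' @return A list of class `bhine_design`.
#' @export
default_design <- function(n_typical = 228, n_unilateral = 40,
                           n_diplegia = 17, n_quadriplegia = 25,
                           rho = 0.8, seed = 20240129) {
  stopifnot(
    n_typical > 0, n_unilateral > 0, n_diplegia > 0, n_quadriplegia > 0,
    rho >= 0, rho <= 1
  )
  structure(
    list(
      n_typical = n_typical, n_unilateral = n_unilateral,
      n_diplegia = n_diplegia, n_quadriplegia = n_quadriplegia,
      ages = hine_ages(), rho = rho, seed = seed
    ),
    class = "bhine_design"
  )
}

## --- truncated normal (base-stats implementation) ---------------------------

# quantiles of N(mean, sd) truncated to [lo, hi]
qtnorm <- function(p, mean, sd, lo, hi) {
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  qnorm(p_lo + p * (p_hi - p_lo), mean, sd)
}

#' Moments of the (rounded) truncated normal score distribution
#'
#' `tnorm_moments()` gives the closed-form mean and SD of a normal
#' distribution truncated to `[lo, hi]`. `score_dist_moments()` gives the
#' exact mean and SD of the generator's actual sampling distribution -- the
#' truncated normal rounded to the 0.5-score grid -- by summing over the
#' grid cells. The two agree closely (rounding to a 0.5 grid perturbs the
#' moments only at the second decimal); both are exposed so tests can use
#' whichever distribution they target as the analytic reference.
#'
#' @param mean,sd Parameters of the parent normal.
#' @param lo,hi Truncation bounds.
#' @param step Rounding grid (default 0.5, the score resolution).
#' @return A list with elements `mean` and `sd`.
#' @name tnorm_moments
#' @export
tnorm_moments <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- pnorm(b) - pnorm(a)
  m <- mean + sd * (dnorm(a) - dnorm(b)) / z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
    ((dnorm(a) - dnorm(b)) / z)^2)
  list(mean = m, sd = sqrt(v))
}

#' @rdname tnorm_moments
#' @export
score_dist_moments <- function(mean, sd, lo, hi, step = 0.5) {
  grid <- seq(ceiling(lo / step) * step, floor(hi / step) * step, by = step)
  # rounding cell of each grid point, clipped to the truncation interval
  a <- pmax(grid - step / 2, lo)
  b <- pmin(grid + step / 2, hi)
  z <- pnorm(hi, mean, sd) - pnorm(lo, mean, sd)
  p <- (pnorm(b, mean, sd) - pnorm(a, mean, sd)) / z
  m <- sum(p * grid)
  list(mean = m, sd = sqrt(sum(p * (grid - m)^2)))
}

#' Sample global scores for one group x age
#'
#' Draws from a normal distribution with the spec's mean and SD, truncated
#' to the spec's observed range and rounded to the 0.5-point resolution of
#' the global score.
#'
#' @param spec One row of [default_score_specs()] (or any list with `mean`,
#'   `sd`, `min`, `max`).
#' @param n Number of draws.
#' @param seed Optional integer seed (applied locally).
#' @return Numeric vector of scores on the 0.5 grid within
#'   `[spec$min, spec$max]`.
#' @export
sample_global_scores <- function(spec, n, seed = NULL) {
  stopifnot(n > 0)
  if (spec$mean < spec$min || spec$mean > spec$max || spec$sd <= 0) {
    abort("infeasible score spec: need min <= mean <= max and sd > 0")
  }
  run <- function() {
    x <- qtnorm(runif(n), spec$mean, spec$sd, spec$min, spec$max)
    pmin(pmax(round(x / 0.5) * 0.5, spec$min), spec$max)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

## --- asymmetry counts: truncated geometric fitted to the median -------------

# Truncated geometric weights q^(k - lo) on {lo, ..., hi}. q is fitted so the
# distribution's median equals the target: for median == lo a fixed q = 0.45
# puts a clear majority of mass at lo while keeping the whole range
# reachable; otherwise q solves (F(m-1) + F(m))/2 = 0.5, centring the median
# bin on the 0.5 quantile (q > 1, an increasing profile, is allowed when the
# target median sits high in the range).
fit_asym_q <- function(median, lo, hi) {
  stopifnot(lo <= median, median <= hi)
  if (median == lo) {
    return(0.45)
  }
  cdf_mid <- function(q) {
    k <- lo:hi
    w <- q^(k - lo)
    cdf <- cumsum(w) / sum(w)
    (cdf[median - lo] + cdf[median - lo + 1]) / 2 - 0.5
  }
  uniroot(cdf_mid, c(1e-6, 25), tol = 1e-10)$root
}

asym_probs <- function(spec) {
  q <- fit_asym_q(spec$median, spec$min, spec$max)
  k <- spec$min:spec$max
  w <- q^(k - spec$min)
  w / sum(w)
}

#' Sample per-exam asymmetry counts
#'
#' Draws integer asymmetry counts from a truncated geometric distribution
#' on `[spec$min, spec$max]` whose parameter is fitted so the distribution's
#' median equals the published median for that subtype and age.
#'
#' @param spec One row of [default_asymmetry_specs()].
#' @param n Number of draws.
#' @param seed Optional integer seed (applied locally).
#' @return Integer vector of counts.
#' @export
sample_asymmetry_counts <- function(spec, n, seed = NULL) {
  stopifnot(n > 0)
  p <- asym_probs(spec)
  run <- function() sample(spec$min:spec$max, n, replace = TRUE, prob = p)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

## --- item-level allocation ---------------------------------------------------

# Asymmetric items carry scores on the half grid {0.5, 1.5, 2.5} (the two
# sides differ by one column), so k asymmetric items fix the fractional part
# of the reachable global scores at 0.5 * (k mod 2).
feasible_target <- function(target, n_asym) {
  lo <- 0.5 * n_asym
  hi <- 33 - 0.5 * n_asym
  if (n_asym %% 2 == 1) {
    t <- floor(target) + 0.5 # nearest x.5
  } else {
    t <- round_half_up(target) # nearest integer
  }
  min(max(t, lo), hi)
}

#' Construct item responses realizing a target global score
#'
#' Builds a full set of 11 item responses whose item scores sum to the
#' target global score (to the nearest value reachable given the number of
#' asymmetric items) with exactly `asymmetry_target` paired items responding
#' differently on the two sides. Asymmetric items are given sides one
#' column apart, so each carries a half-point score.
#'
#' Scores are spread by repeatedly decrementing a random item among those
#' currently at the highest score, which keeps item profiles flat unless the
#' target is very low. For typical-outcome infants the three age-related
#' items start depressed at the younger ages (scores 0--1 at 3 months,
#' 1--2 at 6 months, with roughly a third at 1) -- optimal responses on
#' these items emerge only after 6 months -- and are raised only when a high
#' target score requires it.
#'
#' @param target_global_score Target in 0--33.
#' @param group `"typical"`, `"cp_unilateral"`, `"cp_diplegia"`, or
#'   `"cp_quadriplegia"` (controls the age-related depression only).
#' @param age_months Assessment age.
#' @param asymmetry_target Number of asymmetric paired items (0--6).
#' @param seed Optional integer seed (applied locally).
#' @param items Item table, as returned by [hine_items()].
#' @return A one-row tibble of exam response columns (no `subject_id`/
#'   `age_months`).
#' @export
allocate_items <- function(target_global_score, group, age_months,
                           asymmetry_target = 0, seed = NULL,
                           items = hine_items()) {
  assert_ages(age_months)
  n_paired <- sum(items$paired)
  if (target_global_score < 0 || target_global_score > 33) {
    abort("`target_global_score` must be in [0, 33]")
  }
  if (asymmetry_target < 0 || asymmetry_target > n_paired) {
    abort(sprintf("`asymmetry_target` must be in 0..%d (number of paired items)", n_paired))
  }
  if (target_global_score < 0.5 * asymmetry_target ||
    target_global_score > 33 - 0.5 * asymmetry_target) {
    abort(sprintf(
      "target %s unreachable with %d asymmetric items (each scores 0.5-2.5, so the global score must lie in [%s, %s])",
      format(target_global_score), asymmetry_target,
      format(0.5 * asymmetry_target), format(33 - 0.5 * asymmetry_target)
    ))
  }
  run <- function() {
    target <- feasible_target(target_global_score, asymmetry_target)
    asym_items <- sample(items$item_id[items$paired], asymmetry_target)
    is_asym <- items$item_id %in% asym_items
    floor_s <- ifelse(is_asym, 0.5, 0)
    cap_s <- ifelse(is_asym, 2.5, 3)
    score <- cap_s
    # depressed starting scores for age-related items in typical infants
    if (group == "typical" && age_months <= 6) {
      age_rel <- items$age_related
      base <- if (age_months == 3) {
        sample(0:1, sum(age_rel), replace = TRUE)
      } else {
        sample(0:2, sum(age_rel), replace = TRUE, prob = c(0.15, 0.25, 0.60))
      }
      score[age_rel] <- pmin(pmax(base + 0.5 * is_asym[age_rel], floor_s[age_rel]), cap_s[age_rel])
    }
    gap <- sum(score) - target
    while (gap > 0.5) { # all moves are whole columns; parity already matches
      movable <- which(score > floor_s)
      pick <- movable[score[movable] == max(score[movable])]
      i <- if (length(pick) > 1) sample(pick, 1) else pick
      score[i] <- score[i] - 1
      gap <- gap - 1
    }
    # raises (only reachable via depressed age-related starts) fill from the
    # top, so a high target lifts near-optimal items before consuming the
    # low scores that make these items lag at 3-6 months
    while (gap < -0.5) {
      movable <- which(score < cap_s)
      pick <- movable[score[movable] == max(score[movable])]
      i <- if (length(pick) > 1) sample(pick, 1) else pick
      score[i] <- score[i] + 1
      gap <- gap + 1
    }
    # emit response columns
    cols <- list()
    for (j in seq_len(nrow(items))) {
      id <- items$item_id[j]
      if (!items$paired[j]) {
        cols[[id]] <- as.integer(score[j])
      } else if (!is_asym[j]) {
        cols[[paste0(id, "_left")]] <- as.integer(score[j])
        cols[[paste0(id, "_right")]] <- as.integer(score[j])
      } else {
        sides <- sample(c(floor(score[j]), ceiling(score[j])))
        cols[[paste0(id, "_left")]] <- as.integer(sides[1])
        cols[[paste0(id, "_right")]] <- as.integer(sides[2])
      }
    }
    as_tibble(cols)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

## --- full study --------------------------------------------------------------

#' Simulate a full longitudinal screening study
#'
#' Generates a synthetic cohort with the statistical structure of the
#' validation study: every subject is examined at 3, 6, 9, and 12 months;
#' global scores follow the group's published truncated-normal profile at
#' each age, tied across ages within subject by a Gaussian copula (pairwise
#' latent correlation `design$rho`), so individual trajectories rise with
#' age as the group means do; asymmetry counts follow the published
#' subtype profiles, with the typical cohort receiving a single-asymmetry
#' exam at frequency 10/228; item responses are then constructed to realize
#' each exam's global score and asymmetry count. Fully reproducible under
#' `design$seed`.
#'
#' @param design Study design from [default_design()].
#' @param score_specs Score distribution table, see [default_score_specs()].
#' @param asym_specs Asymmetry profile table, see
#'   [default_asymmetry_specs()].
#' @param items Item table, as returned by [hine_items()].
#' @return A list with `exams` (one row per subject x age, the exam CSV
#'   schema) and `outcomes` (one row per subject).
#' @examples
#' study <- simulate_study(default_design(n_typical = 10, n_unilateral = 3,
#'   n_diplegia = 3, n_quadriplegia = 3, seed = 99))
#' dim(study$exams)
#' @export
simulate_study <- function(design = default_design(),
                           score_specs = default_score_specs(),
                           asym_specs = default_asymmetry_specs(),
                           items = hine_items()) {
  groups <- tibble(
    group = c("typical", "cp_unilateral", "cp_diplegia", "cp_quadriplegia"),
    n = c(
      design$n_typical, design$n_unilateral,
      design$n_diplegia, design$n_quadriplegia
    )
  )
  n_paired <- sum(items$paired)
  withr::with_seed(design$seed, {
    subjects <- groups |>
      tidyr::uncount(.data$n) |>
      mutate(
        subject_id = sprintf("S%04d", row_number()),
        latent = rnorm(dplyr::n())
      )
    exams <- subjects[rep(seq_len(nrow(subjects)), each = length(design$ages)), ] |>
      mutate(age_months = rep(design$ages, nrow(subjects))) |>
      mutate(
        quantile = pnorm(
          sqrt(design$rho) * .data$latent +
            sqrt(1 - design$rho) * rnorm(dplyr::n())
        )
      ) |>
      left_join(score_specs, by = c("group", "age_months")) |>
      mutate(
        target = pmin(pmax(
          round(qtnorm(.data$quantile, .data$mean, .data$sd, .data$min, .data$max) / 0.5) * 0.5,
          .data$min
        ), .data$max)
      )
    # per-exam asymmetry targets
    exams$asym <- 0L
    for (g in c("cp_unilateral", "cp_diplegia", "cp_quadriplegia")) {
      for (a in design$ages) {
        rows <- which(exams$group == g & exams$age_months == a)
        spec <- asym_specs[asym_specs$group == g & asym_specs$age_months == a, ]
        exams$asym[rows] <- sample_asymmetry_counts(spec, length(rows))
      }
    }
    typ <- which(exams$group == "typical")
    exams$asym[typ] <- rbinom(length(typ), 1, 10 / 228)
    # clamp to what the target score can carry
    exams$asym <- pmin(
      exams$asym,
      pmin(floor(exams$target / 0.5), floor((33 - exams$target) / 0.5)),
      n_paired
    )
    responses <- purrr::pmap(
      list(exams$target, exams$group, exams$age_months, exams$asym),
      function(t, g, a, k) allocate_items(t, g, a, k, items = items)
    ) |>
      bind_rows()
    list(
      exams = bind_cols(
        exams[, c("subject_id", "age_months")],
        responses
      )[, exam_columns(items)] |> as_tibble(),
      outcomes = subjects |>
        mutate(
          outcome = ifelse(.data$group == "typical", "typical", "cp"),
          cp_subtype = dplyr::case_when(
            .data$group == "cp_unilateral" ~ "unilateral",
            .data$group == "cp_diplegia" ~ "bilateral_diplegia",
            .data$group == "cp_quadriplegia" ~ "bilateral_quadriplegia",
            TRUE ~ NA_character_
          )
        ) |>
        select("subject_id", "outcome", "cp_subtype")
    )
  })
}

#' Write a simulated study to exam and outcome CSVs
#'
#' @param study A list with `exams` and `outcomes`, as returned by
#'   [simulate_study()].
#' @param exam_path,outcome_path Output CSV paths.
#' @return `study`, invisibly.
#' @export
write_study <- function(study, exam_path, outcome_path) {
  write_exams(study$exams, exam_path)
  write_outcomes(study$outcomes, outcome_path)
  invisible(study)
}
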