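toy <- tibble::tibble(
  score = c(10, 12, 25, 26),
  cp = c(TRUE, TRUE, FALSE, FALSE)
)

test_that("confusion counts follow the low-score-positive rule", {
  expect_equal(
    as.list(confusion_at(toy, 0)),
    list(tp = 0L, fp = 0L, tn = 2L, fn = 2L)
  )
  expect_equal(
    as.list(confusion_at(toy, 34)),
    list(tp = 2L, fp = 2L, tn = 0L, fn = 0L)
  )
  expect_equal(
    as.list(confusion_at(toy, 22)),
    list(tp = 2L, fp = 0L, tn = 2L, fn = 0L)
  )
})

test_that("metrics match their defining formulas, undefined as NA", {
  m <- diag_metrics(list(tp = 72, fp = 18, tn = 210, fn = 10))
  expect_equal(m$ppv, 0.80)
  expect_equal(round_half_up(m$npv, 4), 0.9545)
  expect_equal(round_half_up(m$accuracy, 4), 0.9097)

  perfect <- diag_metrics(list(tp = 82, fp = 0, tn = 228, fn = 0))
  expect_true(all(unlist(perfect) == 1))

  none_called <- diag_metrics(list(tp = 0, fp = 0, tn = 5, fn = 5))
  expect_true(is.na(none_called$ppv))
  expect_equal(none_called$specificity, 1)

  withr::with_seed(701, {
    for (i in 1:20) {
      cts <- as.list(stats::setNames(sample(0:50, 4, replace = TRUE), c("tp", "fp", "tn", "fn")))
      m <- diag_metrics(cts)
      with(cts, {
        expect_equal(m$sensitivity, tp / (tp + fn))
        expect_equal(m$accuracy, (tp + tn) / (tp + fp + tn + fn))
        # accuracy = sens * prev + spec * (1 - prev)
        prev <- (tp + fn) / (tp + fp + tn + fn)
        expect_equal(m$accuracy, m$sensitivity * prev + m$specificity * (1 - prev))
      })
    }
  })
})

test_that("rate reconstruction rounds counts half-up before recomputing", {
  m3 <- metrics_from_rates(0.88, 0.92, n_pos = 82, n_neg = 228)
  expect_equal(as.list(m3[c("tp", "fp", "tn", "fn")]), list(tp = 72, fp = 18, tn = 210, fn = 10))
  expect_equal(round_half_up(m3$ppv, 2), 0.80)
  m12 <- metrics_from_rates(1, 0.86, n_pos = 82, n_neg = 228)
  expect_equal(m12$fn, 0)
  expect_equal(m12$npv, 1)
  expect_equal(metrics_from_rates(1, 1, 10, 10)$accuracy, 1)
})

test_that("ROC sweep covers both corners and matches hand enumeration", {
  sep <- roc_points(toy)
  expect_true(any(sep$sensitivity == 1 & sep$specificity == 1))
  expect_equal(sep$sensitivity[1], 0)
  expect_equal(sep$fpr[nrow(sep)], 1)
  expect_true(all(diff(sep$sensitivity) >= 0))

  flat <- roc_points(tibble::tibble(score = rep(5, 4), cp = c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(nrow(flat), 2)
  expect_equal(flat$sensitivity, c(0, 1))
  expect_equal(flat$fpr, c(0, 1))

  # 6 observations with a tie across classes, enumerated by hand:
  # CP scores {10, 20, 20}, typical {20, 25, 30}; candidates 10,20,25,30,31
  six <- tibble::tibble(
    score = c(10, 20, 20, 20, 25, 30),
    cp = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  )
  pts <- roc_points(six)
  expect_equal(pts$threshold, c(10, 20, 25, 30, 31))
  expect_equal(pts$sensitivity, c(0, 1 / 3, 1, 1, 1))
  expect_equal(pts$specificity, c(1, 1, 2 / 3, 1 / 3, 0))
  expect_error(roc_points(tibble::tibble(score = 1:3, cp = rep(TRUE, 3))), "both classes")
})

test_that("Liu cut-point maximizes sens x spec with smallest-threshold ties", {
  d <- tibble::tibble(
    score = c(10, 12, 25, 26, 27),
    cp = c(TRUE, TRUE, FALSE, FALSE, FALSE)
  )
  fit <- liu_cutpoint(d)
  expect_equal(fit$threshold, 25)
  expect_equal(fit$sensitivity, 1)
  expect_equal(fit$specificity, 1)
  expect_false(fit$degenerate)

  flat <- liu_cutpoint(tibble::tibble(score = rep(7, 6), cp = rep(c(TRUE, FALSE), 3)))
  expect_true(flat$degenerate)
  expect_equal(flat$threshold, 7)

  withr::with_seed(702, {
    for (i in 1:200) {
      d <- random_labeled(sample(1:8, 1), sample(1:8, 1), lo = 0, hi = 10)
      ig <- i %% 2 == 0
      expect_equal(liu_cutpoint(d, integer_grid = ig)$threshold, oracle_liu(d, ig))
    }
  })
})

test_that("rank-based AUC equals pairwise and trapezoidal computations", {
  sep <- tibble::tibble(score = c(1, 2, 30, 31), cp = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(auc_mw(sep), 1)
  tied <- tibble::tibble(score = rep(4, 6), cp = rep(c(TRUE, FALSE), 3))
  expect_equal(auc_mw(tied), 0.5)
  five <- tibble::tibble(
    score = c(3, 8, 8, 12, 20, 8, 14, 20, 26, 30),
    cp = rep(c(TRUE, FALSE), each = 5)
  )
  expect_equal(auc_mw(five), oracle_auc(five))

  withr::with_seed(703, {
    for (i in 1:50) {
      d <- random_labeled(sample(2:20, 1), sample(2:20, 1), lo = 0, hi = 12)
      expect_equal(auc_mw(d), oracle_auc(d), tolerance = 1e-12)
      expect_equal(auc_mw(d), trapezoid_area(roc_points(d)), tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(704, {
    for (i in 1:10) {
      d <- random_labeled(15, 25)
      ref <- pROC::auc(pROC::roc(
        response = d$cp, predictor = d$score,
        direction = ">", levels = c(FALSE, TRUE), quiet = TRUE
      ))
      expect_equal(auc_mw(d), as.numeric(ref), tolerance = 1e-12)
    }
  })
})

test_that("stratified bootstrap is reproducible and degenerates sensibly", {
  d <- random_labeled(20, 30)
  ci1 <- bootstrap_ci(d, auc_mw, B = 100, seed = 9)
  ci2 <- bootstrap_ci(d, auc_mw, B = 100, seed = 9)
  expect_equal(ci1, ci2)
  const <- bootstrap_ci(d, function(x) 0.42, B = 50, seed = 1)
  expect_equal(const$conf_low, const$conf_high)
  expect_equal(const$conf_low, 0.42)
  # named-vector statistics give one interval per term
  multi <- bootstrap_ci(
    d, function(x) c(auc = auc_mw(x), sens = diag_metrics(confusion_at(x, 6))$sensitivity),
    B = 50, seed = 2
  )
  expect_equal(multi$term, c("auc", "sens"))
  expect_true(all(multi$conf_low <= multi$estimate + 1e-12))
  expect_true(all(multi$conf_high >= multi$estimate - 1e-12))
})

test_that("bootstrap percentile coverage is near nominal on normal scores", {
  # true AUC for N(0,1) vs N(1,1) is pnorm(1/sqrt(2))
  true_auc <- pnorm(1 / sqrt(2))
  withr::with_seed(705, {
    hits <- 0
    for (i in 1:40) {
      d <- tibble::tibble(
        score = c(rnorm(40), rnorm(40, 1)),
        cp = rep(c(TRUE, FALSE), each = 40)
      )
      ci <- bootstrap_ci(d, auc_mw, B = 200, level = 0.9)
      hits <- hits + (ci$conf_low <= true_auc && true_auc <= ci$conf_high)
    }
    expect_gte(hits / 40, 0.7) # loose band around the 90% nominal level
  })
})
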