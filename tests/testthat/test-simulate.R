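test_that("score specs transcribe the published group distributions", {
  specs <- default_score_specs()
  expect_equal(nrow(specs), 16)
  typ3 <- dplyr::filter(specs, group == "typical", age_months == 3)
  expect_equal(unlist(typ3[, c("mean", "sd", "min", "max")]),
    c(mean = 23, sd = 2.2, min = 18, max = 30)
  )
  typ12 <- dplyr::filter(specs, group == "typical", age_months == 12)
  expect_equal(unlist(typ12[, c("mean", "sd", "min", "max")]),
    c(mean = 31, sd = 1.6, min = 27, max = 33)
  )
  # subtype SDs default to range/4
  quad12 <- dplyr::filter(specs, group == "cp_quadriplegia", age_months == 12)
  expect_equal(quad12$sd, (21 - 10) / 4)
  expect_true(all(specs$min <= specs$mean & specs$mean <= specs$max))
})

test_that("truncated-normal moments agree with numeric integration", {
  for (p in list(c(23, 2.2, 18, 30), c(12.5, 2.75, 10, 21), c(31, 1.6, 27, 33))) {
    m <- tnorm_moments(p[1], p[2], p[3], p[4])
    z <- stats::integrate(function(x) dnorm(x, p[1], p[2]), p[3], p[4])$value
    m1 <- stats::integrate(function(x) x * dnorm(x, p[1], p[2]), p[3], p[4])$value / z
    m2 <- stats::integrate(function(x) x^2 * dnorm(x, p[1], p[2]), p[3], p[4])$value / z
    expect_equal(m$mean, m1, tolerance = 1e-8)
    expect_equal(m$sd, sqrt(m2 - m1^2), tolerance = 1e-8)
  }
})

test_that("score sampling respects bounds, grid, seed, and analytic moments", {
  spec <- dplyr::filter(default_score_specs(), group == "typical", age_months == 3)
  x <- sample_global_scores(spec, 2000, seed = 31)
  expect_true(all(x >= spec$min & x <= spec$max))
  expect_true(all(x * 2 == floor(x * 2)))
  expect_equal(x, sample_global_scores(spec, 2000, seed = 31))

  big <- sample_global_scores(spec, 50000, seed = 32)
  expect_equal(mean(big), tnorm_moments(spec$mean, spec$sd, spec$min, spec$max)$mean,
    tolerance = 0.1 / 23
  )
  gm <- score_dist_moments(spec$mean, spec$sd, spec$min, spec$max)
  expect_lt(abs(mean(big) - gm$mean), 3 * sd(big) / sqrt(length(big)))

  bad <- spec
  bad$mean <- 40
  expect_error(sample_global_scores(bad, 10), "infeasible")
})

test_that("asymmetry sampling hits the published medians and bounds", {
  specs <- default_asymmetry_specs()
  dip <- dplyr::filter(specs, group == "cp_diplegia", age_months == 3)
  x <- sample_asymmetry_counts(dip, 5000, seed = 41)
  expect_true(all(x %in% 0:2))
  expect_equal(median(x), 0)

  uni9 <- dplyr::filter(specs, group == "cp_unilateral", age_months == 9)
  expect_equal(median(sample_asymmetry_counts(uni9, 10000, seed = 42)), 2)
  uni3 <- dplyr::filter(specs, group == "cp_unilateral", age_months == 3)
  expect_equal(median(sample_asymmetry_counts(uni3, 10000, seed = 43)), 1)
  quad <- dplyr::filter(specs, group == "cp_quadriplegia", age_months == 12)
  expect_equal(median(sample_asymmetry_counts(quad, 10000, seed = 44)), 0)
})

test_that("item allocation realizes target scores and asymmetry counts", {
  all3 <- allocate_items(33, "typical", 12, 0, seed = 51)
  expect_true(all(unlist(all3) == 3))
  all0 <- allocate_items(0, "cp_quadriplegia", 3, 0, seed = 52)
  expect_true(all(unlist(all0) == 0))

  withr::with_seed(53, {
    for (i in 1:60) {
      target <- sample(seq(0, 33, 0.5), 1)
      k <- sample(0:6, 1)
      if (target < 0.5 * k || target > 33 - 0.5 * k) next
      group <- sample(c("typical", "cp_unilateral", "cp_quadriplegia"), 1)
      age <- sample(c(3L, 6L, 9L, 12L), 1)
      resp <- allocate_items(target, group, age, k)
      exam <- dplyr::bind_cols(
        tibble::tibble(subject_id = "A", age_months = age), resp
      )
      scored <- score_exams(exam)
      expect_equal(scored$asymmetry_count, k)
      # reached to the nearest feasible half point (integer when k is even)
      expect_lte(abs(scored$global_score - target), 0.5)
      expect_equal(scored$global_score, briefhine:::feasible_target(target, k))
    }
  })

  expect_error(allocate_items(33, "typical", 12, 2), "unreachable")
  expect_error(allocate_items(0.5, "typical", 12, 3), "unreachable")
  expect_error(allocate_items(10, "typical", 12, 7), "asymmetry_target")
  expect_error(allocate_items(40, "typical", 12), "target_global_score")
})

test_that("simulated studies have the study's shape and validate throughout", {
  design <- default_design(
    n_typical = 20, n_unilateral = 5, n_diplegia = 4,
    n_quadriplegia = 3, seed = 61
  )
  study <- simulate_study(design)
  expect_equal(nrow(study$exams), 32 * 4)
  expect_equal(nrow(study$outcomes), 32)
  expect_silent(validate_exams(study$exams))
  expect_silent(validate_outcomes(study$outcomes))
  expect_equal(sum(study$outcomes$outcome == "cp"), 12)
  # reproducible under the design seed
  study2 <- simulate_study(design)
  expect_equal(study$exams, study2$exams)

  # typical exams carry at most one asymmetry
  scored <- score_exams(study$exams)
  typ_ids <- study$outcomes$subject_id[study$outcomes$outcome == "typical"]
  expect_true(all(scored$asymmetry_count[scored$subject_id %in% typ_ids] <= 1))
})

test_that("a full copula ties each subject to one quantile across ages", {
  design <- default_design(
    n_typical = 60, n_unilateral = 2, n_diplegia = 2,
    n_quadriplegia = 2, rho = 1, seed = 62
  )
  scored <- score_exams(simulate_study(design)$exams)
  typ <- scored[grepl("^S0", scored$subject_id) & scored$subject_id %in%
    sprintf("S%04d", 1:60), c("subject_id", "age_months", "global_score")]
  wide <- tidyr::pivot_wider(typ, names_from = age_months, values_from = global_score)
  # comonotone trajectories: rank order preserved between ages (ties aside)
  expect_gte(cor(wide$`3`, wide$`12`, method = "spearman"), 0.9)
  expect_gte(cor(wide$`6`, wide$`9`, method = "spearman"), 0.9)
})

test_that("generator marginals recover the spec moments at depth", {
  specs <- default_score_specs()
  withr::with_seed(63, {
    for (i in seq_len(nrow(specs))) {
      s <- specs[i, ]
      x <- sample_global_scores(s, 10000)
      ref <- score_dist_moments(s$mean, s$sd, s$min, s$max)
      expect_lt(abs(mean(x) - ref$mean), 3 * ref$sd / sqrt(10000))
      expect_lt(abs(sd(x) - ref$sd), 3 * ref$sd / sqrt(2 * 10000))
    }
  })
})
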