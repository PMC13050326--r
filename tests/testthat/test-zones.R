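test_that("candidate thresholds are unique sorted scores plus sentinels", {
  cand <- candidate_thresholds(toy8())
  expect_length(cand, 10)
  expect_identical(cand[2:9], sort(unique(toy8()$score)))
  expect_lt(cand[1], min(toy8()$score))
  expect_gt(cand[10], max(toy8()$score))

  dup <- tibble::tibble(case_id = letters[1:8], score = rep(0.5, 8),
                        label = rep(c(0L, 1L), 4))
  expect_length(candidate_thresholds(dup), 3)

  distinct <- random_cohort(25, seed = 1)
  expect_length(candidate_thresholds(distinct), 25 + 2)
})

test_that("rule-in boundaries are the attained infimum of qualifying thresholds", {
  expect_identical(rule_in_boundary(toy8(), 1), 0.7)
  expect_identical(rule_in_boundary(toy8(), 0.8), 0.4)

  # every score at/above the top positive belongs to a negative
  topneg <- tibble::tibble(case_id = letters[1:4],
                           score = c(0.9, 0.8, 0.5, 0.2),
                           label = c(0L, 1L, 1L, 0L))
  expect_identical(rule_in_boundary(topneg, 1), NA_real_)
})

test_that("rule-out boundaries are the attained supremum of qualifying thresholds", {
  expect_identical(rule_out_boundary(toy8(), 1), 0.4)
  expect_identical(rule_out_boundary(toy8(), 0.75), 0.7) # NPV(0.7) = 0.8, NPV(0.8) fails

  ties <- tibble::tibble(case_id = letters[1:4], score = rep(0.5, 4),
                         label = c(1L, 0L, 0L, 1L))
  # constant NPV = proportion of negatives (0.5) below any qualifying target
  expect_identical(rule_out_boundary(ties, 0.9), NA_real_)
})

test_that("the three zones partition the worked example as derived by hand", {
  part <- make_partition(toy8(), 1, 1)
  d <- tidy(part)
  expect_setequal(d$score[d$zone == "rule_in"], c(0.9, 0.8, 0.7))
  expect_setequal(d$score[d$zone == "rule_out"], c(0.3, 0.2, 0.1))
  expect_setequal(d$score[d$zone == "gray"], c(0.6, 0.4))
  expect_false(part$clipped)
  g <- glance(part)
  expect_identical(g$achieved_ppv, 1)
  expect_identical(g$achieved_npv, 1)
})

test_that("coinciding boundaries yield an empty Gray Zone without clipping", {
  part <- make_partition(toy8(), alpha_plus = 1, alpha_minus = 0.75)
  expect_identical(part$tau_plus, 0.7)
  expect_identical(part$tau_minus, 0.7)
  expect_false(part$clipped)
  expect_identical(gray_fraction(part), 0)
})

test_that("overlapping zones under lenient targets are clipped with a warning", {
  expect_warning(
    part <- make_partition(toy8(), alpha_plus = 0.75, alpha_minus = 0.75),
    class = "saroc_clipped_warning"
  )
  expect_true(part$clipped)
  expect_identical(part$tau_minus, part$tau_plus)
  expect_identical(sum(table(tidy(part)$zone)), 8L)
})

test_that("a separable cohort automates everything at maximal stringency", {
  sep <- tibble::tibble(case_id = letters[1:6],
                        score = c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1),
                        label = c(1L, 1L, 1L, 0L, 0L, 0L))
  part <- make_partition(sep, 1, 1)
  expect_identical(gray_fraction(part), 0)
  expect_identical(gray_area(sep, part), 0)
})

test_that("boundary searches match the exhaustive oracle on random cohorts", {
  for (seed in 1:60) {
    cohort <- random_cohort(sample(4:50, 1), seed = seed, ties = seed %% 3 == 0)
    alpha <- sample(c(0.6, 0.75, 0.9, 0.95, 1), 1)
    expect_identical(rule_in_boundary(cohort, alpha),
                     oracle_rule_in(cohort$score, cohort$label, alpha))
    expect_identical(rule_out_boundary(cohort, alpha),
                     oracle_rule_out(cohort$score, cohort$label, alpha))
  }
})

test_that("boundary monotonicity and in-sample guarantees hold", {
  grid <- seq(0.5, 1, by = 0.025)
  for (seed in 1:15) {
    cohort <- random_cohort(40, seed = seed, ties = TRUE)
    tau_p <- vapply(grid, function(a) rule_in_boundary(cohort, a), numeric(1))
    tau_m <- vapply(grid, function(a) rule_out_boundary(cohort, a), numeric(1))
    # treat EMPTY as +Inf (rule-in) / -Inf (rule-out) for the ordering check;
    # NaN diffs arise only between two EMPTY boundaries, which is consistent
    dp <- diff(ifelse(is.na(tau_p), Inf, tau_p))
    dm <- diff(ifelse(is.na(tau_m), -Inf, tau_m))
    expect_true(all(dp >= 0 | is.nan(dp)))
    expect_true(all(dm <= 0 | is.nan(dm)))
    for (a in c(0.8, 0.95, 1)) {
      part <- suppressWarnings(make_partition(cohort, a, a))
      if (!part$rule_in_empty && !part$clipped) {
        expect_gte(part$achieved_ppv, a)
      }
      if (!part$rule_out_empty && !part$clipped) {
        expect_gte(part$achieved_npv, a)
      }
    }
  }
})

test_that("zone assignments are invariant under strictly increasing transforms", {
  for (seed in 1:10) {
    cohort <- random_cohort(50, seed = seed, ties = TRUE)
    transformed <- cohort
    transformed$score <- stats::plogis(5 * cohort$score - 2.5)
    for (a in c(0.8, 1)) {
      pa <- suppressWarnings(make_partition(cohort, a, a))
      pb <- suppressWarnings(make_partition(transformed, a, a))
      expect_identical(as.character(tidy(pa)$zone), as.character(tidy(pb)$zone))
      expect_equal(gray_area(cohort, pa), gray_area(transformed, pb))
    }
  }
})

test_that("safety profiles report the symmetric workload trade-off", {
  prof <- safety_profile(toy8(), alphas = c(0.75, 0.8, 1.0))
  expect_equal(prof$gray_fraction, c(0, 0, 0.25))

  default_prof <- safety_profile(toy8())
  expect_identical(nrow(default_prof), 101L)
  expect_error(safety_profile(toy8(), alphas = numeric(0)),
               class = "saroc_usage_error")

  # non-decreasing workload in the symmetric safety level
  for (seed in 1:8) {
    cohort <- random_cohort(60, seed = seed, ties = TRUE)
    p <- safety_profile(cohort, alphas = seq(0.5, 1, by = 0.01))
    expect_true(all(diff(p$gray_fraction) >= -1e-12))
    expect_true(all(diff(p$gamma_area) >= -1e-12))
  }
})

test_that("fixed-side profile modes hold the stated side constant", {
  prof <- safety_profile(toy8(), alphas = c(0.8, 1), mode = "fixed_alpha_minus",
                         fixed = 0.9)
  expect_true(all(prof$alpha_minus == 0.9))
  expect_identical(prof$alpha_plus, c(0.8, 1))
  expect_error(safety_profile(toy8(), mode = "fixed_alpha_plus"),
               class = "saroc_usage_error")
})
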