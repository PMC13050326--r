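test_that("pathway A reports the workload implied by both safety targets", {
  pol <- solve_constraints(toy8(), alpha_plus = 1, alpha_minus = 1)
  expect_identical(pol$pathway, "A")
  expect_identical(pol$p_g, 0.25)
  expect_identical(c(pol$n_tp, pol$n_fp, pol$n_tn, pol$n_fn, pol$n_gray),
                   c(3L, 0L, 3L, 0L, 2L))
})

test_that("pathway A reproduces the symmetric zone partitions exactly", {
  for (seed in 1:10) {
    cohort <- random_cohort(45, seed = seed, ties = TRUE)
    for (a in c(0.8, 0.95, 1)) {
      pol <- suppressWarnings(solve_constraints(cohort, alpha_plus = a, alpha_minus = a))
      part <- suppressWarnings(make_partition(cohort, a, a))
      expect_identical(pol$tau_plus, part$tau_plus)
      expect_identical(pol$tau_minus, part$tau_minus)
      expect_identical(pol$p_g, gray_fraction(part))
    }
  }
})

test_that("pathway C maximizes rule-in reliability within the workload budget", {
  pol <- solve_constraints(toy8(), alpha_minus = 1, p_g_max = 0.25)
  expect_identical(pol$pathway, "C")
  expect_identical(pol$tau_minus, 0.4)
  expect_identical(pol$tau_plus, 0.7)
  expect_identical(pol$achieved_alpha_plus, 1)
  expect_identical(pol$p_g, 0.25)
})

test_that("pathway B maximizes rule-out reliability within the workload budget", {
  # unconstrained budget: the best achievable NPV is 1 at tau_minus = 0.4
  pol <- solve_constraints(toy8(), alpha_plus = 1, p_g_max = 1)
  expect_identical(pol$pathway, "B")
  expect_identical(pol$tau_plus, 0.7)
  expect_identical(pol$tau_minus, 0.4)
  expect_identical(pol$achieved_alpha_minus, 1)

  # binding budget: only tau_minus = 0.7 keeps the Gray Zone within 10%
  tight <- solve_constraints(toy8(), alpha_plus = 1, p_g_max = 0.1)
  expect_identical(tight$tau_minus, 0.7)
  expect_identical(tight$achieved_alpha_minus, 0.8)
  expect_identical(tight$p_g, 0)
})

test_that("constraint pathways respect the workload budget whenever feasible", {
  for (seed in 1:15) {
    cohort <- random_cohort(40, seed = seed, ties = TRUE)
    alpha <- sample(c(0.8, 0.9, 1), 1)
    budget <- sample(c(0, 0.1, 0.3, 0.6), 1)
    for (pw in c("B", "C")) {
      pol <- if (pw == "B") {
        solve_constraints(cohort, alpha_plus = alpha, p_g_max = budget)
      } else {
        solve_constraints(cohort, alpha_minus = alpha, p_g_max = budget)
      }
      if (pol$feasible) expect_lte(pol$p_g, budget + 1e-9)
      expect_true(is.na(pol$tau_plus) || is.na(pol$tau_minus) ||
                    pol$tau_minus <= pol$tau_plus)
    }
  }
})

test_that("constraint count is validated", {
  expect_error(solve_constraints(toy8(), alpha_plus = 1),
               class = "saroc_usage_error")
  expect_error(solve_constraints(toy8(), alpha_plus = 1, alpha_minus = 1,
                                 p_g_max = 0.2),
               class = "saroc_usage_error")
  expect_error(solve_constraints(toy8(), alpha_plus = 1.5, alpha_minus = 1),
               class = "saroc_usage_error")
})

test_that("utility maximization resolves the worked example with its tie-break", {
  pol <- maximize_utility(toy8(), utility_spec(1, 1, 0, 0, 0))
  expect_identical(pol$total_utility, 7)
  expect_identical(pol$tau_minus, 0.4)
  expect_identical(pol$tau_plus, 0.4)
  tab <- tidy(pol)
  expect_identical(sum(tab$n), 8L)
  expect_identical(sum(tab$total), 7)
})

test_that("degenerate utility specs produce the expected corner policies", {
  all_gray <- maximize_utility(toy8(), utility_spec(0, 0, 0, 0, 1))
  expect_identical(all_gray$n_gray, 8L)
  expect_identical(all_gray$total_utility, 8)

  sep <- tibble::tibble(case_id = letters[1:6],
                        score = c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1),
                        label = c(1L, 1L, 1L, 0L, 0L, 0L))
  perfect <- maximize_utility(sep, utility_spec(1, 1, -10, -10, 0))
  expect_identical(perfect$total_utility, 6)
  expect_identical(perfect$n_fp + perfect$n_fn, 0L)
})

test_that("policy enumeration covers all valid pairs and matches the optimizer", {
  spec <- utility_spec(1, 1, 0, 0, 0)
  tab <- enumerate_policies(toy8(), spec)
  expect_identical(nrow(tab), 55L) # 10 candidates -> 10*11/2 ordered pairs
  expect_identical(max(tab$u_total), maximize_utility(toy8(), spec)$total_utility)

  zeros <- enumerate_policies(toy8(), utility_spec(0, 0, 0, 0, 0))
  expect_true(all(zeros$u_total == 0))

  big <- random_cohort(30, seed = 1)
  expect_error(enumerate_policies(big, spec, cap = 10),
               class = "saroc_usage_error")
})

test_that("the optimizer equals brute-force enumeration on random instances", {
  for (seed in 1:60) {
    cohort <- random_cohort(sample(4:60, 1), seed = seed, ties = seed %% 2 == 0)
    set.seed(seed + 10000)
    u <- round(stats::runif(5, -5, 5), 2)
    spec <- utility_spec(u[1], u[2], u[3], u[4], u[5])
    pol <- maximize_utility(cohort, spec)
    ref <- oracle_best_policy(cohort$score, cohort$label, u[1], u[2], u[3], u[4], u[5])
    expect_equal(pol$total_utility, ref$u)
    expect_identical(pol$tau_minus, ref$tau_minus)
    expect_identical(pol$tau_plus, ref$tau_plus)
  }
})

test_that("raising the deferral utility weakly grows the optimal Gray Zone", {
  for (seed in 1:20) {
    cohort <- random_cohort(35, seed = seed)
    set.seed(seed + 20000)
    u <- round(stats::runif(4, -4, 4), 2)
    sizes <- vapply(c(-2, 0, 2), function(ug) {
      maximize_utility(cohort, utility_spec(u[1], u[2], u[3], u[4], ug))$n_gray
    }, integer(1))
    expect_true(all(diff(sizes) >= 0))
  }
})
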