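test_that("bootstrap intervals are seed-reproducible and degenerate correctly", {
  sep <- tibble::tibble(case_id = sprintf("c%02d", 1:20),
                        score = rep(c(1, 0), each = 10),
                        label = rep(c(1L, 0L), each = 10))
  ci <- bootstrap_interval(sep, "auc", B = 100, seed = 7)
  expect_identical(ci$point, 1)
  expect_identical(ci$lower, 1)
  expect_identical(ci$upper, 1)

  cohort <- random_cohort(80, seed = 11)
  a1 <- bootstrap_interval(cohort, "gamma_area", alpha = 0.95, B = 100, seed = 3)
  a2 <- bootstrap_interval(cohort, "gamma_area", alpha = 0.95, B = 100, seed = 3)
  expect_identical(a1, a2)
  a3 <- bootstrap_interval(cohort, "gamma_area", alpha = 0.95, B = 100, seed = 4)
  expect_false(identical(a1$lower, a3$lower) && identical(a1$upper, a3$upper))

  expect_error(bootstrap_interval(cohort, "gamma_area", B = 100),
               class = "saroc_usage_error")
  expect_error(bootstrap_interval(cohort, "auc", B = 1),
               class = "saroc_usage_error")
})

test_that("the bootstrap matches an independent reimplementation of its recipe", {
  cohort <- random_cohort(30, seed = 21)
  B <- 200
  seed <- 17
  res <- bootstrap_interval(cohort, "auc", B = B, seed = seed)

  # independent re-implementation: same documented RNG recipe
  # (set.seed; per replicate, sample.int(n, n, TRUE), rejecting single-class
  # draws), but the statistic computed by pairwise comparison
  s <- cohort$score
  y <- cohort$label
  n <- length(s)
  vals <- numeric(B)
  set.seed(seed)
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (any(y[idx] == 1L) && any(y[idx] == 0L)) break
    }
    vals[b] <- oracle_auc(s[idx], y[idx])
  }
  ci <- unname(stats::quantile(vals, c(0.025, 0.975)))
  expect_equal(res$lower, ci[1], tolerance = 1e-12)
  expect_equal(res$upper, ci[2], tolerance = 1e-12)
  expect_equal(res$point, oracle_auc(s, y), tolerance = 1e-12)
})

test_that("boundary refitting per replicate can be frozen on request", {
  cohort <- random_cohort(60, seed = 31)
  refit <- bootstrap_interval(cohort, "gray_fraction", alpha = 1, B = 50, seed = 5)
  frozen <- bootstrap_interval(cohort, "gray_fraction", alpha = 1, B = 50, seed = 5,
                               refit_boundaries = FALSE)
  expect_identical(refit$point, frozen$point) # same full-cohort point estimate
  expect_false(identical(refit[c("lower", "upper")], frozen[c("lower", "upper")]))
})

test_that("prevalence targeting rounds half to even and conserves negatives", {
  cohort <- tibble::tibble(
    case_id = sprintf("c%04d", 1:1000),
    score = c(stats::runif(600, 0, 0.7), stats::runif(400, 0.3, 1)),
    label = c(rep(0L, 600), rep(1L, 400))
  )
  sweep <- prevalence_sweep(cohort, prevalences = c(0.01, 0.4), alpha_minus = 1,
                            B = 5, seed = 2, keep_cohorts = TRUE)
  expect_identical(unique(sweep$n_pos_target[sweep$prevalence == 0.01]), 6)
  expect_identical(unique(sweep$n_pos_target[sweep$prevalence == 0.4]), 400)

  reps <- attr(sweep, "replicates")
  neg_ref <- sort(cohort$score[cohort$label == 0L])
  for (r in reps) {
    expect_identical(sort(r$score[r$label == 0L]), neg_ref)
    expect_true(all(r$score[r$label == 1L] %in% cohort$score[cohort$label == 1L]))
  }

  realized <- dplyr::filter(sweep, metric == "realized_prevalence")
  expect_true(all(abs(realized$value - realized$prevalence) <=
                    1 / (600 + realized$n_pos_target)))

  expect_error(prevalence_sweep(cohort, prevalences = 0.0001, alpha_minus = 1,
                                B = 2, seed = 1),
               class = "saroc_validation_error")
  expect_error(prevalence_sweep(cohort, prevalences = 1.2, alpha_minus = 1,
                                B = 2, seed = 1),
               class = "saroc_usage_error")

  smry <- summarize_sweep(sweep)
  expect_true(all(smry$lower <= smry$upper))
})

test_that("paired model differences are antisymmetric and rank-invariant", {
  a <- random_cohort(40, seed = 41)
  self <- paired_model_difference(a, a, alpha_minus = 1, B = 50, seed = 1)
  expect_identical(self$point, 0L)
  expect_identical(c(self$lower, self$upper), c(0, 0))

  b <- a
  b$score <- stats::plogis(4 * a$score - 2) # strictly increasing transform
  mono <- paired_model_difference(a, b, alpha_minus = 1, B = 50, seed = 1)
  expect_identical(mono$point, 0L)

  ab <- paired_model_difference(a, b, alpha_minus = 0.9, B = 50, seed = 9)
  ba <- paired_model_difference(b, a, alpha_minus = 0.9, B = 50, seed = 9)
  expect_identical(ab$point, -ba$point)
})

test_that("a constructed pair shows the expected rule-out gain", {
  labels <- c(rep(0L, 10), rep(1L, 10))
  ids <- sprintf("c%02d", 1:20)
  # model A: three negatives drift above the minimum positive score, so only
  # seven negatives can be ruled out at NPV = 1
  score_a <- c(seq(0.10, 0.22, by = 0.02), 0.55, 0.60, 0.65,
               seq(0.50, 0.95, by = 0.05))
  # model B: all ten negatives fall below every positive
  score_b <- c(seq(0.10, 0.22, by = 0.02), 0.29, 0.295, 0.30,
               seq(0.50, 0.95, by = 0.05))
  a <- tibble::tibble(case_id = ids, score = score_a, label = labels)
  b <- tibble::tibble(case_id = ids, score = score_b, label = labels)
  diff <- paired_model_difference(a, b, alpha_minus = 1, B = 50, seed = 3)
  expect_identical(diff$point, 3L)

  mismatched <- b
  mismatched$case_id[1] <- "zz"
  expect_error(paired_model_difference(a, mismatched, alpha_minus = 1,
                                       B = 10, seed = 1),
               class = "saroc_validation_error")
})

test_that("zone concordance tables conserve margins", {
  pa <- make_partition(toy8(), 1, 1)
  conc_self <- zone_concordance(pa, pa)
  off_diag <- conc_self$n[as.character(conc_self$zone_a) != as.character(conc_self$zone_b)]
  expect_true(all(off_diag == 0))
  expect_identical(sum(conc_self$n), 8L)

  flipped <- toy8()
  flipped$score <- 1 - flipped$score
  pb <- make_partition(flipped, 1, 1)
  conc <- zone_concordance(pa, pb)
  expect_identical(sum(conc$n), 8L)
  # direct counting oracle
  joint <- table(tidy(pa)$zone, tidy(pb)$zone)
  for (i in seq_len(nrow(conc))) {
    expect_identical(conc$n[i], as.integer(joint[as.character(conc$zone_a[i]),
                                                 as.character(conc$zone_b[i])]))
  }
  # margins equal each partition's zone sizes
  expect_equal(as.integer(tapply(conc$n, conc$zone_a, sum)),
               as.integer(table(tidy(pa)$zone)))
})

test_that("reader stratification matches direct counting", {
  cohort <- toy8()
  cohort$reader_call <- c(1L, 0L, 1L, 1L, 1L, 0L, 0L, 1L)
  strat <- stratify_reader_outcomes(
    cohort, zone_specs = tibble::tibble(zone = c("rule_in", "gray", "rule_out"),
                                        alpha = c(1, 1, 1))
  )
  part <- tidy(make_partition(cohort, 1, 1))
  for (i in seq_len(nrow(strat))) {
    d <- part[part$zone == strat$zone[i], ]
    expect_identical(strat$n[i], nrow(d))
    expect_identical(strat$n_fp[i], sum(d$reader_call == 1L & d$label == 0L))
    expect_identical(strat$accuracy[i],
                     sum(d$reader_call == d$label) / nrow(d))
  }
  expect_identical(sum(strat$n), 8L)
})

test_that("reader stratification handles perfect, biased and missing readers", {
  perfect <- toy8()
  perfect$reader_call <- perfect$label
  strat <- stratify_reader_outcomes(perfect)
  expect_true(all(strat$accuracy[strat$n > 0] == 1))

  overcaller <- tibble::tibble(
    case_id = sprintf("c%02d", 1:10),
    score = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.2, 0.15, 0.1, 0.05, 0.02),
    label = c(1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L),
    reader_call = rep(1L, 10)
  )
  st2 <- stratify_reader_outcomes(
    overcaller, zone_specs = tibble::tibble(zone = "rule_out", alpha = 1)
  )
  expect_identical(st2$accuracy, 0) # all-negative zone, reader calls all positive

  partial <- perfect
  partial$reader_call[1:3] <- NA_integer_
  expect_message(
    st3 <- stratify_reader_outcomes(
      partial, zone_specs = tibble::tibble(zone = "rule_in", alpha = 1)
    ),
    "3 cases"
  )
  expect_identical(st3$n, nrow(dplyr::filter(
    tidy(make_partition(perfect, 1, 1)), zone == "rule_in"
  )) - 3L)
})
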