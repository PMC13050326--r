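# Uncertainty quantification: percentile bootstrap, prevalence-shift
# resampling, paired two-model comparison, reader-outcome stratification.
#
# RNG contract: every operation takes an explicit seed, draws from a single
# R Mersenne-Twister stream initialized with set.seed(seed), consumes
# replicate draws sequentially (a rejected single-class resample consumes
# its draw and the redraw is the next one), and restores the caller's RNG
# state afterwards. Identical seeds give bit-identical results.

.draw_resample <- function(n, y) {
  # Resample indices, rejecting single-class draws (they leave ROC/zone
  # statistics undefined); rejections are counted by the caller.
  sample.int(n, n, replace = TRUE)
}

.stat_fun <- function(statistic, alpha) {
  switch(statistic,
    auc = function(s, y) .auc(s, y),
    gamma_area = function(s, y) .zone_metrics(s, y, alpha)[["gamma_area"]],
    gray_fraction = function(s, y) .zone_metrics(s, y, alpha)[["gray_fraction"]],
    rule_out_tn_count = function(s, y) {
      tm <- .rule_out(.thresh_table(s, y), alpha)
      sum(y == 0L & s < .eff_minus(tm))
    }
  )
}

#' Percentile bootstrap confidence interval for a zone or ROC statistic
#'
#' Resamples the cohort with replacement `B` times, recomputes the
#' statistic on each resample (re-deriving the zone boundaries inside each
#' replicate unless `refit_boundaries = FALSE`), and reports the 2.5th and
#' 97.5th percentiles of the resampled values as the 95% interval.
#' Resamples that lose one of the two classes are rejected and redrawn; the
#' count is reported.
#'
#' @param cohort A cohort tibble with both classes present.
#' @param statistic One of `"auc"`, `"gamma_area"`, `"gray_fraction"`,
#'   `"rule_out_tn_count"`.
#' @param alpha Symmetric safety level for the zone statistics (ignored for
#'   `"auc"`).
#' @param B Number of bootstrap resamples (default 2000).
#' @param seed Integer seed; identical seeds give bit-identical intervals.
#' @param refit_boundaries If `FALSE`, freeze the zone boundaries derived
#'   from the full cohort instead of re-deriving them per replicate.
#' @return A one-row tibble: `statistic`, `alpha`, `point`, `lower`,
#'   `upper`, `B`, `seed`, `n_redrawn`.
#' @export
bootstrap_interval <- function(cohort, statistic = c("auc", "gamma_area",
                                                     "gray_fraction",
                                                     "rule_out_tn_count"),
                               alpha = NULL, B = 2000, seed = 1,
                               refit_boundaries = TRUE) {
  cohort <- check_cohort(cohort, require_both_classes = TRUE)
  statistic <- match.arg(statistic)
  if (B < 2) stop_usage("`B` must be at least 2.")
  if (statistic != "auc") {
    if (is.null(alpha)) stop_usage("`alpha` is required for zone statistics.")
    .check_alpha(alpha, "alpha")
  } else {
    alpha <- NA_real_
  }
  s <- cohort$score
  y <- cohort$label
  n <- length(s)

  if (refit_boundaries || statistic == "auc") {
    f <- .stat_fun(statistic, alpha)
  } else {
    tt <- .thresh_table(s, y)
    b <- .boundaries(tt, alpha, alpha, warn_clip = FALSE)
    f <- switch(statistic,
      gamma_area = function(ss, yy) .gamma_area(ss, yy, b$tau_plus, b$tau_minus),
      gray_fraction = function(ss, yy) {
        mean(.zone_of(ss, b$tau_plus, b$tau_minus) == "gray")
      },
      rule_out_tn_count = function(ss, yy) {
        sum(yy == 0L & ss < .eff_minus(b$tau_minus))
      }
    )
  }

  point <- f(s, y)
  vals <- numeric(B)
  n_redrawn <- 0L
  .with_seed(seed, {
    for (b_i in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (any(y[idx] == 1L) && any(y[idx] == 0L)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 100L * B) {
          stop_validation("Too many single-class resamples; cohort is too unbalanced to bootstrap.")
        }
      }
      vals[b_i] <- f(s[idx], y[idx])
    }
  })
  n_undefined <- sum(is.na(vals))
  if (n_undefined > B / 2) {
    stop_validation("Statistic undefined on more than half of the resamples.")
  }
  if (n_redrawn > 0) {
    inform(sprintf("bootstrap_interval: %d single-class resamples redrawn.", n_redrawn))
  }
  ci <- quantile(vals, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  tibble::tibble(
    statistic = statistic, alpha = alpha, point = point,
    lower = ci[1], upper = ci[2], B = as.integer(B),
    seed = as.integer(seed), n_redrawn = n_redrawn
  )
}

#' Prevalence-shift resampling of the positive class
#'
#' Emulates deployment under a different disease prevalence while holding
#' the score distributions fixed: every replicate keeps the complete
#' negative cohort unchanged and resamples positive cases with replacement
#' to the count implied by the target prevalence
#' (`round(n_neg * p / (1 - p))`, round-half-to-even). Zone boundaries and
#' workload metrics are recomputed per replicate under a symmetric safety
#' level equal to `alpha_minus`.
#'
#' @param cohort A cohort tibble with both classes present.
#' @param prevalences Target prevalences, each in `(0, 1)`.
#' @param alpha_minus Rule-out safety level applied (symmetrically) in each
#'   replicate.
#' @param B Replicates per target prevalence.
#' @param seed Integer seed.
#' @param keep_cohorts If `TRUE`, attach every resampled replicate cohort as
#'   the `"replicates"` attribute (a list of score/label tibbles), so the
#'   conservation of the negative set can be inspected directly.
#' @return A tidy long tibble with columns `prevalence`, `n_pos_target`,
#'   `replicate`, `metric`, `value`; metrics are the per-replicate zone
#'   quantities (`tau_plus`, `tau_minus`, `n_rule_in`, `n_rule_out`,
#'   `rule_out_tn`, `gray_fraction`, `gamma_area`) plus
#'   `realized_prevalence`. Summarize with [summarize_sweep()].
#' @export
prevalence_sweep <- function(cohort, prevalences, alpha_minus, B = 100, seed = 1,
                             keep_cohorts = FALSE) {
  cohort <- check_cohort(cohort, require_both_classes = TRUE)
  .check_alpha(alpha_minus, "alpha_minus")
  if (any(prevalences <= 0 | prevalences >= 1)) {
    stop_usage("`prevalences` must lie strictly inside (0, 1).")
  }
  s_neg <- cohort$score[cohort$label == 0L]
  s_pos <- cohort$score[cohort$label == 1L]
  n_neg <- length(s_neg)
  y_template <- function(n_pos) c(rep(0L, n_neg), rep(1L, n_pos))
  kept <- if (keep_cohorts) list() else NULL

  rows <- .with_seed(seed, {
    purrr::map(prevalences, function(p) {
      n_pos_t <- round(n_neg * p / (1 - p))
      if (n_pos_t < 1) {
        stop_validation(sprintf(
          "Target prevalence %.4g implies zero positive cases for %d negatives.",
          p, n_neg
        ))
      }
      y_rep <- y_template(n_pos_t)
      purrr::map(seq_len(B), function(b) {
        pos_draw <- s_pos[sample.int(length(s_pos), n_pos_t, replace = TRUE)]
        if (keep_cohorts) {
          kept[[length(kept) + 1L]] <<- tibble::tibble(
            score = c(s_neg, pos_draw), label = y_rep
          )
        }
        m <- .zone_metrics(c(s_neg, pos_draw), y_rep, alpha_minus)
        tibble::tibble(
          prevalence = p, n_pos_target = n_pos_t, replicate = b,
          metric = c(names(m), "realized_prevalence"),
          value = c(unname(m), n_pos_t / (n_neg + n_pos_t))
        )
      })
    })
  })
  out <- dplyr::bind_rows(rows)
  if (keep_cohorts) attr(out, "replicates") <- kept
  out
}

#' Percentile summary of a prevalence sweep
#'
#' @param sweep Output of [prevalence_sweep()].
#' @param probs Percentiles to report (default 2.5/50/97.5).
#' @return A tibble with one row per (prevalence, metric): `lower`,
#'   `median`, `upper` (or the requested percentiles).
#' @export
summarize_sweep <- function(sweep, probs = c(0.025, 0.5, 0.975)) {
  sweep |>
    dplyr::group_by(.data$prevalence, .data$metric) |>
    dplyr::summarise(
      lower = quantile(.data$value, probs[1], na.rm = TRUE, names = FALSE),
      median = quantile(.data$value, probs[2], na.rm = TRUE, names = FALSE),
      upper = quantile(.data$value, probs[3], na.rm = TRUE, names = FALSE),
      .groups = "drop"
    )
}

.check_paired <- function(cohort_a, cohort_b) {
  a <- check_cohort(cohort_a, require_both_classes = TRUE)
  b <- check_cohort(cohort_b, require_both_classes = TRUE)
  if (!setequal(a$case_id, b$case_id) || nrow(a) != nrow(b)) {
    stop_validation("The two cohorts must cover identical case sets.")
  }
  b <- b[match(a$case_id, b$case_id), ]
  if (!identical(a$label, b$label)) {
    stop_validation("Labels disagree between the two cohorts for the same cases.")
  }
  list(a = a, b = b)
}

#' Paired bootstrap comparison of two models' Rule-out Safe Zones
#'
#' For two models scoring the same cases, the statistic is the number of
#' true negatives ruled out by model B at `alpha_minus` minus the same
#' count for model A; the interval comes from a paired case-level
#' bootstrap (both models are resampled on the same case indices, and the
#' rule-out boundary is re-derived for each model inside every replicate).
#'
#' @param cohort_a,cohort_b Cohort tibbles over identical cases (same
#'   `case_id` sets and labels, different scores).
#' @param alpha_minus Rule-out safety level.
#' @param B Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return A one-row tibble: `statistic`, `alpha`, `point`, `lower`,
#'   `upper`, `B`, `seed`, `n_redrawn`.
#' @export
paired_model_difference <- function(cohort_a, cohort_b, alpha_minus,
                                    B = 2000, seed = 1) {
  .check_alpha(alpha_minus, "alpha_minus")
  pair <- .check_paired(cohort_a, cohort_b)
  sa <- pair$a$score
  sb <- pair$b$score
  y <- pair$a$label
  n <- length(y)
  f <- .stat_fun("rule_out_tn_count", alpha_minus)
  point <- f(sb, y) - f(sa, y)
  vals <- numeric(B)
  n_redrawn <- 0L
  .with_seed(seed, {
    for (b_i in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (any(y[idx] == 1L) && any(y[idx] == 0L)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 100L * B) {
          stop_validation("Too many single-class resamples.")
        }
      }
      vals[b_i] <- f(sb[idx], y[idx]) - f(sa[idx], y[idx])
    }
  })
  ci <- quantile(vals, c(0.025, 0.975), names = FALSE)
  tibble::tibble(
    statistic = "rule_out_tn_count_difference", alpha = alpha_minus,
    point = point, lower = ci[1], upper = ci[2],
    B = as.integer(B), seed = as.integer(seed), n_redrawn = n_redrawn
  )
}

#' Cross-model zone concordance
#'
#' Contingency table of zone assignments for the same cases under two
#' partitions (e.g. two models at the same safety level).
#'
#' @param partition_a,partition_b `sa_partition` objects over identical
#'   case sets.
#' @return A 9-row tibble `zone_a`, `zone_b`, `n`; margins equal each
#'   partition's zone sizes.
#' @export
zone_concordance <- function(partition_a, partition_b) {
  if (!inherits(partition_a, "sa_partition") || !inherits(partition_b, "sa_partition")) {
    stop_usage("Both arguments must be sa_partition objects.")
  }
  a <- partition_a$data
  b <- partition_b$data
  if (!setequal(a$case_id, b$case_id) || nrow(a) != nrow(b)) {
    stop_validation("Partitions must cover identical case sets.")
  }
  b <- b[match(a$case_id, b$case_id), ]
  tab <- table(zone_a = a$zone, zone_b = b$zone)
  out <- tibble::as_tibble(tab)
  out$n <- as.integer(out$n)
  out$zone_a <- factor(out$zone_a, levels = levels(a$zone))
  out$zone_b <- factor(out$zone_b, levels = levels(a$zone))
  dplyr::arrange(out, .data$zone_a, .data$zone_b)
}

#' Human-reader outcomes stratified by AI safety zones
#'
#' For each requested zone (at its safety level), tabulates the reader's
#' TP/TN/FP/FN outcomes among cases assigned to that zone and the overall
#' reader accuracy there. Each safety level is partitioned independently
#' (symmetric policy), so nested zones at different levels are reported
#' side by side. Cases without a reader call are excluded (with a message
#' stating the count).
#'
#' @param cohort A cohort tibble with a `reader_call` column.
#' @param zone_specs A data frame with columns `zone`
#'   (`"rule_in"`/`"gray"`/`"rule_out"`) and `alpha`; defaults to rule-in
#'   and rule-out at 1.00/0.95/0.90 plus the Gray Zone at 0.90.
#' @return A tibble with one row per requested zone: counts, outcome
#'   proportions and `accuracy` (`NA` for empty zones).
#' @export
stratify_reader_outcomes <- function(cohort, zone_specs = NULL) {
  cohort <- check_cohort(cohort, require_both_classes = TRUE)
  if (!"reader_call" %in% names(cohort)) {
    stop_usage("Cohort has no `reader_call` column.")
  }
  if (is.null(zone_specs)) {
    zone_specs <- tibble::tibble(
      zone = c("rule_in", "rule_in", "rule_in", "gray",
               "rule_out", "rule_out", "rule_out"),
      alpha = c(1, 0.95, 0.90, 0.90, 1, 0.95, 0.90)
    )
  }
  if (!all(c("zone", "alpha") %in% names(zone_specs))) {
    stop_usage("`zone_specs` needs columns `zone` and `alpha`.")
  }
  n_missing <- sum(is.na(cohort$reader_call))
  if (n_missing > 0) {
    inform(sprintf(
      "stratify_reader_outcomes: %d cases without a reader call excluded.", n_missing
    ))
  }

  partitions <- lapply(unique(zone_specs$alpha), function(a) {
    make_partition(cohort, alpha_plus = a, alpha_minus = a)
  })
  names(partitions) <- as.character(unique(zone_specs$alpha))

  rows <- purrr::pmap(zone_specs[c("zone", "alpha")], function(zone, alpha) {
    part <- partitions[[as.character(alpha)]]
    d <- part$data
    d <- d[d$zone == zone & !is.na(d$reader_call), ]
    n <- nrow(d)
    n_tp <- sum(d$reader_call == 1L & d$label == 1L)
    n_tn <- sum(d$reader_call == 0L & d$label == 0L)
    n_fp <- sum(d$reader_call == 1L & d$label == 0L)
    n_fn <- sum(d$reader_call == 0L & d$label == 1L)
    tibble::tibble(
      zone = zone, alpha = alpha, n = n,
      n_tp = n_tp, n_tn = n_tn, n_fp = n_fp, n_fn = n_fn,
      prop_tp = if (n > 0) n_tp / n else NA_real_,
      prop_tn = if (n > 0) n_tn / n else NA_real_,
      prop_fp = if (n > 0) n_fp / n else NA_real_,
      prop_fn = if (n > 0) n_fn / n else NA_real_,
      accuracy = if (n > 0) (n_tp + n_tn) / n else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}
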