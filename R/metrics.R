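# Threshold-level confusion statistics, AUC, Youden threshold, and the
# Gray-Zone workload metrics.
#
# Conventions (used everywhere in the package): a positive call is
# score >= tau (closed at tau); a negative call is score < tau. PPV/NPV at
# thresholds where the respective call set is empty are UNDEFINED and
# reported as NA_real_; such thresholds never qualify for a Safe Zone.

#' Confusion counts at a decision threshold
#'
#' @param cohort A cohort tibble.
#' @param tau Decision threshold; cases with `score >= tau` are called
#'   positive.
#' @return A one-row tibble with `tau`, `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion_at(toy8_cohort(), 0.7)
#' @export
confusion_at <- function(cohort, tau) {
  cohort <- check_cohort(cohort)
  cc <- .confusion(cohort$score, cohort$label, tau)
  tibble::tibble(tau = tau, tp = cc[["tp"]], fp = cc[["fp"]],
                 tn = cc[["tn"]], fn = cc[["fn"]])
}

#' Positive and negative predictive value at a threshold
#'
#' `ppv_at()` is the fraction of positive calls (`score >= tau`) that are
#' truly positive; `npv_at()` the fraction of negative calls (`score < tau`)
#' that are truly negative. Both return `NA_real_` (UNDEFINED) when the
#' respective call set is empty; this is a value, not an error.
#'
#' @inheritParams confusion_at
#' @return A double scalar, possibly `NA_real_`.
#' @export
ppv_at <- function(cohort, tau) {
  cohort <- check_cohort(cohort)
  cc <- .confusion(cohort$score, cohort$label, tau)
  denom <- cc[["tp"]] + cc[["fp"]]
  if (denom == 0) NA_real_ else cc[["tp"]] / denom
}

#' @rdname ppv_at
#' @export
npv_at <- function(cohort, tau) {
  cohort <- check_cohort(cohort)
  cc <- .confusion(cohort$score, cohort$label, tau)
  denom <- cc[["tn"]] + cc[["fn"]]
  if (denom == 0) NA_real_ else cc[["tn"]] / denom
}

#' ROC operating point at a threshold
#'
#' @inheritParams confusion_at
#' @return A one-row tibble with `tau`, `tpr`, `fpr`.
#' @export
roc_point_at <- function(cohort, tau) {
  cohort <- check_cohort(cohort, require_both_classes = TRUE)
  tibble::tibble(
    tau = tau,
    tpr = .tpr_at(cohort$score, cohort$label, tau),
    fpr = .fpr_at(cohort$score, cohort$label, tau)
  )
}

#' Confusion statistics at every candidate threshold
#'
#' Evaluates the full empirical operating landscape: one row per candidate
#' threshold (the cohort's unique scores bracketed by a low and a high
#' sentinel), with confusion counts, TPR/FPR, and PPV/NPV (`NA` where
#' undefined). No score binning is applied.
#'
#' @param cohort A cohort tibble with both classes present.
#' @return A tibble with columns `tau`, `tp`, `fp`, `tn`, `fn`, `tpr`,
#'   `fpr`, `ppv`, `npv`, ordered by ascending `tau`.
#' @export
threshold_metrics <- function(cohort) {
  cohort <- check_cohort(cohort, require_both_classes = TRUE)
  tt <- .thresh_table(cohort$score, cohort$label)
  tibble::tibble(
    tau = tt$tau, tp = tt$tp, fp = tt$fp, tn = tt$tn, fn = tt$fn,
    tpr = tt$tpr, fpr = tt$fpr, ppv = tt$ppv, npv = tt$npv
  )
}

#' Candidate decision thresholds of a cohort
#'
#' Ascending unique scores, prefixed by a sentinel below the minimum score
#' and suffixed by a sentinel above the maximum; every achievable confusion
#' table corresponds to a candidate.
#'
#' @param cohort A cohort tibble.
#' @return A numeric vector of candidate thresholds.
#' @export
candidate_thresholds <- function(cohort) {
  cohort <- check_cohort(cohort)
  .candidates(cohort$score)
}

#' Area under the empirical ROC curve
#'
#' Computed as the rank statistic: the probability that a random positive
#' case outscores a random negative case, with ties counted one half. This
#' equals trapezoidal integration of the empirical ROC curve.
#'
#' @param cohort A cohort tibble with both classes present.
#' @return A double in `[0, 1]`.
#' @examples
#' sa_auc(toy8_cohort()) # 15/16
#' @export
sa_auc <- function(cohort) {
  cohort <- check_cohort(cohort, require_both_classes = TRUE)
  .auc(cohort$score, cohort$label)
}

#' Youden-optimal threshold
#'
#' Returns a candidate threshold maximizing Youden's J = TPR - FPR
#' (sensitivity + specificity - 1). Ties are broken toward the higher TPR and
#' then the lower threshold, favoring sensitivity in screening settings.
#'
#' @param cohort A cohort tibble with both classes present.
#' @return A one-row tibble with `theta`, `j`, `tpr`, `fpr`.
#' @export
youden_threshold <- function(cohort) {
  cohort <- check_cohort(cohort, require_both_classes = TRUE)
  tt <- .thresh_table(cohort$score, cohort$label)
  j <- tt$tpr - tt$fpr
  best <- order(-j, -tt$tpr, tt$tau)[1L]
  tibble::tibble(theta = tt$tau[best], j = j[best],
                 tpr = tt$tpr[best], fpr = tt$fpr[best])
}

#' Gray Zone Area
#'
#' The rectangle in ROC space quantifying the cost of indecision:
#' `FPR(tau_minus) * (1 - TPR(tau_plus))`. An empty Rule-out Zone
#' contributes `FPR = 1`; an empty Rule-in Zone contributes `TPR = 0`, so
#' the area degrades gracefully to 1 when nothing is automatable. The area
#' is always evaluated at the attained boundary thresholds themselves; when
#' lenient targets make the two Safe Zones overlap, the per-case partition
#' clips the rule-out boundary, but the area keeps the unclipped boundary
#' so that it remains exactly monotone in the symmetric safety level.
#'
#' @param cohort The cohort the boundaries were derived from.
#' @param partition A [make_partition()] result (or its boundaries) for
#'   this cohort; supplying boundaries from a different cohort is an error.
#' @return A double in `[0, 1]`.
#' @export
gray_area <- function(cohort, partition) {
  cohort <- check_cohort(cohort, require_both_classes = TRUE)
  b <- .as_boundaries(partition)
  fp <- cohort_fingerprint(cohort$score, cohort$label)
  if (!is.null(b$fingerprint) && !identical(b$fingerprint, fp)) {
    stop_usage("Boundaries were derived from a different cohort (fingerprint mismatch).")
  }
  .gamma_area(cohort$score, cohort$label, b$tau_plus, b$tau_minus)
}

#' Gray-Zone fraction of a partition
#'
#' @param partition A [make_partition()] result.
#' @return The fraction of cases assigned to the Gray Zone.
#' @export
gray_fraction <- function(partition) {
  if (!inherits(partition, "sa_partition")) {
    stop_usage("`partition` must be an sa_partition object.")
  }
  mean(partition$data$zone == "gray")
}
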