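# Operating-policy derivation: the two-of-three constraint pathways and
# exact utility maximization over candidate threshold pairs.

#' Per-case utility specification
#'
#' Per-case utilities for the five possible dispositions of a case under a
#' three-zone policy: true positive / false positive in the Rule-in Zone,
#' true negative / false negative in the Rule-out Zone, and deferral to the
#' Gray Zone. Penalties are negative values.
#'
#' @param u_tp,u_tn,u_fp,u_fn,u_gray Finite per-case utilities.
#' @return An `sa_utility` list.
#' @export
utility_spec <- function(u_tp, u_tn, u_fp, u_fn, u_gray) {
  vals <- c(u_tp = u_tp, u_tn = u_tn, u_fp = u_fp, u_fn = u_fn, u_gray = u_gray)
  if (!all(is.finite(vals))) stop_usage("All utilities must be finite numbers.")
  structure(as.list(vals), class = "sa_utility")
}

.policy_from_taus <- function(cohort, tau_plus, tau_minus, pathway,
                              alpha_plus = NA_real_, alpha_minus = NA_real_,
                              p_g_max = NA_real_, feasible = TRUE,
                              clipped = FALSE, tau_minus_raw = tau_minus,
                              total_utility = NULL, utility_table = NULL) {
  s <- cohort$score
  y <- cohort$label
  n <- length(s)
  tp_eff <- .eff_plus(tau_plus)
  tm_eff <- .eff_minus(tau_minus)
  cc <- .confusion(s, y, tp_eff)
  n_tp <- cc[["tp"]]
  n_fp <- cc[["fp"]]
  n_tn <- sum(y == 0L & s < tm_eff)
  n_fn <- sum(y == 1L & s < tm_eff)
  n_gray <- n - n_tp - n_fp - n_tn - n_fn
  structure(
    list(
      pathway = pathway,
      tau_plus = tau_plus,
      tau_minus = tau_minus,
      rule_in_empty = is.na(tau_plus),
      rule_out_empty = is.na(tau_minus),
      clipped = clipped,
      target_alpha_plus = alpha_plus,
      target_alpha_minus = alpha_minus,
      p_g_max = p_g_max,
      achieved_alpha_plus = if (n_tp + n_fp > 0) n_tp / (n_tp + n_fp) else NA_real_,
      achieved_alpha_minus = if (n_tn + n_fn > 0) n_tn / (n_tn + n_fn) else NA_real_,
      n = n,
      n_tp = n_tp, n_fp = n_fp, n_tn = n_tn, n_fn = n_fn, n_gray = n_gray,
      p_g = n_gray / n,
      gamma_area = .gamma_area(s, y, tau_plus, tau_minus_raw),
      feasible = feasible,
      total_utility = total_utility,
      utility_table = utility_table,
      fingerprint = cohort_fingerprint(s, y)
    ),
    class = "sa_policy"
  )
}

#' @export
print.sa_policy <- function(x, ...) {
  cat(sprintf("<sa_policy>  pathway %s%s\n", x$pathway,
              if (!x$feasible) " (INFEASIBLE under the stated budget)" else ""))
  cat(sprintf(
    "  tau+ = %s, tau- = %s   achieved PPV = %s, NPV = %s\n",
    if (x$rule_in_empty) "EMPTY" else format(x$tau_plus),
    if (x$rule_out_empty) "EMPTY" else format(x$tau_minus),
    format(x$achieved_alpha_plus), format(x$achieved_alpha_minus)
  ))
  cat(sprintf(
    "  counts: TP %d FP %d | gray %d | TN %d FN %d   p_g = %.4g\n",
    x$n_tp, x$n_fp, x$n_gray, x$n_tn, x$n_fn, x$p_g
  ))
  if (!is.null(x$total_utility)) {
    cat(sprintf("  total utility = %.6g\n", x$total_utility))
  }
  invisible(x)
}

#' @describeIn solve_constraints One-row summary tibble of a policy.
#' @param x An `sa_policy` object.
#' @param ... Unused.
#' @export
glance.sa_policy <- function(x, ...) {
  tibble::tibble(
    pathway = x$pathway,
    tau_plus = x$tau_plus, tau_minus = x$tau_minus,
    achieved_alpha_plus = x$achieved_alpha_plus,
    achieved_alpha_minus = x$achieved_alpha_minus,
    n = x$n, n_tp = x$n_tp, n_fp = x$n_fp, n_tn = x$n_tn, n_fn = x$n_fn,
    n_gray = x$n_gray, p_g = x$p_g, gamma_area = x$gamma_area,
    feasible = x$feasible,
    total_utility = x$total_utility %||% NA_real_
  )
}

#' @describeIn solve_constraints Outcome/utility table of a policy (empty
#'   tibble for constraint-derived policies without a utility spec).
#' @export
tidy.sa_policy <- function(x, ...) {
  x$utility_table %||%
    tibble::tibble(outcome = character(), n = integer(),
                   utility = double(), total = double())
}

#' Derive an operating policy from two of three clinical constraints
#'
#' A policy is governed by three parameters: rule-in reliability
#' (`alpha_plus`, a PPV target), rule-out reliability (`alpha_minus`, an NPV
#' target), and workload (`p_g_max`, the maximum acceptable Gray-Zone
#' fraction). Supplying exactly two determines the third:
#'
#' * **A** (`alpha_plus` + `alpha_minus`): partition under both targets and
#'   report the resulting workload `p_g`.
#' * **B** (`alpha_plus` + `p_g_max`): fix the rule-in boundary, then choose
#'   the rule-out boundary maximizing the achieved NPV among candidates that
#'   respect contiguity (`tau_minus <= tau_plus`) and the workload budget;
#'   ties go to the smaller Gray Zone.
#' * **C** (`alpha_minus` + `p_g_max`): symmetric, maximizing achieved PPV.
#'
#' An infeasible budget yields a policy with the offending zone empty and
#' `feasible = FALSE`, not an error.
#'
#' @param cohort A cohort tibble with both classes present.
#' @param alpha_plus,alpha_minus Safety levels in `(0, 1]`, or `NULL`.
#' @param p_g_max Maximum Gray-Zone fraction in `[0, 1]`, or `NULL`.
#' @return An `sa_policy` object.
#' @export
solve_constraints <- function(cohort, alpha_plus = NULL, alpha_minus = NULL,
                              p_g_max = NULL) {
  cohort <- check_cohort(cohort, require_both_classes = TRUE)
  given <- c(alpha_plus = !is.null(alpha_plus),
             alpha_minus = !is.null(alpha_minus),
             p_g_max = !is.null(p_g_max))
  if (sum(given) != 2) {
    stop_usage("Supply exactly two of `alpha_plus`, `alpha_minus`, `p_g_max`.")
  }
  if (!is.null(alpha_plus)) .check_alpha(alpha_plus, "alpha_plus")
  if (!is.null(alpha_minus)) .check_alpha(alpha_minus, "alpha_minus")
  if (!is.null(p_g_max) &&
      (!is.numeric(p_g_max) || length(p_g_max) != 1 || is.na(p_g_max) ||
       p_g_max < 0 || p_g_max > 1)) {
    stop_usage("`p_g_max` must be a single number in [0, 1].")
  }

  s <- cohort$score
  y <- cohort$label
  n <- length(s)
  tt <- .thresh_table(s, y)

  if (given[["alpha_plus"]] && given[["alpha_minus"]]) {
    b <- .boundaries(tt, alpha_plus, alpha_minus)
    return(.policy_from_taus(cohort, b$tau_plus, b$tau_minus, "A",
                             alpha_plus = alpha_plus, alpha_minus = alpha_minus,
                             clipped = b$clipped, tau_minus_raw = b$tau_minus_raw))
  }

  budget <- p_g_max * n + 1e-9
  n_lt <- tt$tn + tt$fn # cases called negative (score < tau) per candidate
  n_ge <- tt$tp + tt$fp

  if (given[["alpha_plus"]]) {
    # Pathway B: tau_plus from alpha_plus; maximize achieved NPV within budget.
    tau_plus <- .rule_in(tt, alpha_plus)
    n_rule_in <- if (is.na(tau_plus)) 0L else n_ge[match(tau_plus, tt$tau)]
    ok <- !is.na(tt$npv) &
      tt$tau <= .eff_plus(tau_plus) &
      (n - n_rule_in - n_lt) <= budget
    if (!any(ok)) {
      feasible <- (n - n_rule_in) <= budget
      return(.policy_from_taus(cohort, tau_plus, NA_real_, "B",
                               alpha_plus = alpha_plus, p_g_max = p_g_max,
                               feasible = feasible))
    }
    idx <- which(ok)
    best <- idx[order(-tt$npv[idx], -tt$tau[idx])[1L]]
    return(.policy_from_taus(cohort, tau_plus, tt$tau[best], "B",
                             alpha_plus = alpha_plus, p_g_max = p_g_max))
  }

  # Pathway C: tau_minus from alpha_minus; maximize achieved PPV within budget.
  tau_minus <- .rule_out(tt, alpha_minus)
  n_rule_out <- if (is.na(tau_minus)) 0L else n_lt[match(tau_minus, tt$tau)]
  ok <- !is.na(tt$ppv) &
    tt$tau >= .eff_minus(tau_minus) &
    (n - n_rule_out - n_ge) <= budget
  if (!any(ok)) {
    feasible <- (n - n_rule_out) <= budget
    return(.policy_from_taus(cohort, NA_real_, tau_minus, "C",
                             alpha_minus = alpha_minus, p_g_max = p_g_max,
                             feasible = feasible))
  }
  idx <- which(ok)
  best <- idx[order(-tt$ppv[idx], tt$tau[idx])[1L]]
  .policy_from_taus(cohort, tt$tau[best], tau_minus, "C",
                    alpha_minus = alpha_minus, p_g_max = p_g_max)
}

.utility_of_counts <- function(n_tp, n_tn, n_fp, n_fn, n_gray, spec) {
  n_tp * spec$u_tp + n_tn * spec$u_tn + n_fp * spec$u_fp +
    n_fn * spec$u_fn + n_gray * spec$u_gray
}

.utility_table <- function(n_tp, n_tn, n_fp, n_fn, n_gray, spec) {
  tibble::tibble(
    outcome = c("TP", "TN", "FP", "FN", "Gray"),
    n = as.integer(c(n_tp, n_tn, n_fp, n_fn, n_gray)),
    utility = c(spec$u_tp, spec$u_tn, spec$u_fp, spec$u_fn, spec$u_gray),
    total = .data$n * .data$utility
  )
}

#' Utility-maximizing operating policy
#'
#' Exact argmax of the total utility
#' `n_TP*U_TP + n_TN*U_TN + n_FP*U_FP + n_FN*U_FN + n_Gray*U_Gray`
#' over all candidate threshold pairs `(tau_minus, tau_plus)` with
#' `tau_minus <= tau_plus`, by systematic search over the candidate grid
#' with prefix-summed counts. Ties are broken deterministically: fewest
#' total errors (`n_fp + n_fn`), then fewest Gray-Zone cases, then the
#' lexicographically smallest `(tau_minus, tau_plus)` pair.
#'
#' @param cohort A cohort tibble with both classes present.
#' @param spec A [utility_spec()].
#' @return An `sa_policy` with `total_utility` and the per-outcome utility
#'   table (`tidy()` on the result).
#' @export
maximize_utility <- function(cohort, spec) {
  cohort <- check_cohort(cohort, require_both_classes = TRUE)
  if (!inherits(spec, "sa_utility")) stop_usage("`spec` must be a utility_spec().")
  s <- cohort$score
  y <- cohort$label
  n <- length(s)
  tt <- .thresh_table(s, y)
  m <- length(tt$tau)
  p_lt <- tt$fn # positives below tau
  n_lt <- tt$tn # negatives below tau

  best <- NULL
  for (j in seq_len(m)) {
    i <- seq_len(j)
    ntp <- rep(tt$tp[j], j)
    nfp <- rep(tt$fp[j], j)
    ntn <- n_lt[i]
    nfn <- p_lt[i]
    ngray <- n - ntp - nfp - ntn - nfn
    u <- ntp * spec$u_tp + ntn * spec$u_tn + nfp * spec$u_fp +
      nfn * spec$u_fn + ngray * spec$u_gray
    errs <- nfp + nfn
    k <- order(-u, errs, ngray, tt$tau[i])[1L]
    cand <- list(u = u[k], errs = errs[k], ngray = ngray[k],
                 tau_minus = tt$tau[k], tau_plus = tt$tau[j],
                 n_tp = ntp[k], n_fp = nfp[k], n_tn = ntn[k], n_fn = nfn[k])
    if (is.null(best) ||
        cand$u > best$u ||
        (cand$u == best$u && (cand$errs < best$errs ||
          (cand$errs == best$errs && (cand$ngray < best$ngray ||
            (cand$ngray == best$ngray && cand$tau_minus < best$tau_minus)))))) {
      best <- cand
    }
  }

  ut <- .utility_table(best$n_tp, best$n_tn, best$n_fp, best$n_fn,
                       best$ngray, spec)
  .policy_from_taus(cohort, best$tau_plus, best$tau_minus, "U",
                    total_utility = best$u, utility_table = ut)
}

#' Enumerate every candidate threshold-pair policy
#'
#' Brute-force table of all valid pairs `(tau_minus, tau_plus)` with
#' `tau_minus <= tau_plus` over the candidate grid, with zone counts and
#' total utility per pair; the utility landscape underlying
#' [maximize_utility()]. The row maximum equals the optimizer's result
#' exactly.
#'
#' @inheritParams maximize_utility
#' @param cap Maximum cohort size (the table is quadratic in the number of
#'   unique scores); above it, an error suggests [maximize_utility()].
#' @return A tibble with one row per pair: `tau_minus`, `tau_plus`,
#'   `n_tp`, `n_fp`, `n_tn`, `n_fn`, `n_gray`, `u_total`.
#' @export
enumerate_policies <- function(cohort, spec, cap = 5000) {
  cohort <- check_cohort(cohort, require_both_classes = TRUE)
  if (!inherits(spec, "sa_utility")) stop_usage("`spec` must be a utility_spec().")
  if (nrow(cohort) > cap) {
    stop_usage(sprintf(
      "Cohort size %d exceeds the enumeration cap (%d); use maximize_utility().",
      nrow(cohort), cap
    ))
  }
  tt <- .thresh_table(cohort$score, cohort$label)
  m <- length(tt$tau)
  n <- tt$n
  j <- rep.int(seq_len(m), times = seq_len(m))
  i <- sequence(seq_len(m))
  ntp <- tt$tp[j]
  nfp <- tt$fp[j]
  ntn <- tt$tn[i]
  nfn <- tt$fn[i]
  ngray <- n - ntp - nfp - ntn - nfn
  u <- ntp * spec$u_tp + ntn * spec$u_tn + nfp * spec$u_fp +
    nfn * spec$u_fn + ngray * spec$u_gray
  tibble::tibble(
    tau_minus = tt$tau[i], tau_plus = tt$tau[j],
    n_tp = ntp, n_fp = nfp, n_tn = ntn, n_fn = nfn, n_gray = ngray,
    u_total = u
  )
}
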