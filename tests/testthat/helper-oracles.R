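# Brute-force oracles, deliberately written as direct definitional loops so
# they share no code path with the package's prefix-sum implementation.

oracle_candidates <- function(s) {
  u <- sort(unique(s))
  c(u[1] - 1, u, u[length(u)] + 1)
}

oracle_ppv <- function(s, y, tau) {
  called <- which(s >= tau)
  if (length(called) == 0) return(NA_real_)
  mean(y[called] == 1L)
}

oracle_npv <- function(s, y, tau) {
  called <- which(s < tau)
  if (length(called) == 0) return(NA_real_)
  mean(y[called] == 0L)
}

oracle_auc <- function(s, y) {
  pos <- s[y == 1L]
  neg <- s[y == 0L]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# Exhaustive scan for the Safe-Zone boundaries: test every candidate
# threshold directly against the safety target.
oracle_rule_in <- function(s, y, alpha_plus) {
  for (tau in oracle_candidates(s)) {
    p <- oracle_ppv(s, y, tau)
    if (!is.na(p) && p >= alpha_plus) return(tau)
  }
  NA_real_
}

oracle_rule_out <- function(s, y, alpha_minus) {
  best <- NA_real_
  for (tau in oracle_candidates(s)) {
    p <- oracle_npv(s, y, tau)
    if (!is.na(p) && p >= alpha_minus) best <- tau
  }
  best
}

oracle_zones <- function(s, alpha_plus_tau, alpha_minus_tau) {
  tp <- if (is.na(alpha_plus_tau)) Inf else alpha_plus_tau
  tm <- if (is.na(alpha_minus_tau)) -Inf else alpha_minus_tau
  if (tm > tp) tm <- tp
  ifelse(s >= tp, "rule_in", ifelse(s < tm, "rule_out", "gray"))
}

# Brute-force utility search over every candidate pair.
oracle_best_policy <- function(s, y, u_tp, u_tn, u_fp, u_fn, u_gray) {
  cand <- oracle_candidates(s)
  n <- length(s)
  best <- NULL
  for (tau_plus in cand) {
    for (tau_minus in cand[cand <= tau_plus]) {
      ntp <- sum(s >= tau_plus & y == 1L)
      nfp <- sum(s >= tau_plus & y == 0L)
      ntn <- sum(s < tau_minus & y == 0L)
      nfn <- sum(s < tau_minus & y == 1L)
      ngray <- n - ntp - nfp - ntn - nfn
      u <- ntp * u_tp + ntn * u_tn + nfp * u_fp + nfn * u_fn + ngray * u_gray
      cand_row <- list(u = u, errs = nfp + nfn, ngray = ngray,
                       tau_minus = tau_minus, tau_plus = tau_plus)
      if (is.null(best) ||
          cand_row$u > best$u ||
          (cand_row$u == best$u && (cand_row$errs < best$errs ||
            (cand_row$errs == best$errs && (cand_row$ngray < best$ngray ||
              (cand_row$ngray == best$ngray &&
                 (cand_row$tau_minus < best$tau_minus ||
                    (cand_row$tau_minus == best$tau_minus &&
                       cand_row$tau_plus < best$tau_plus)))))))) {
        best <- cand_row
      }
    }
  }
  best
}

random_cohort <- function(n, seed, ties = FALSE) {
  set.seed(seed)
  repeat {
    y <- stats::rbinom(n, 1, stats::runif(1, 0.15, 0.85))
    if (any(y == 1) && any(y == 0)) break
  }
  s <- stats::runif(n)
  if (ties) s <- round(s, sample(1:2, 1))
  tibble::tibble(
    case_id = sprintf("c%04d", seq_len(n)),
    score = s,
    label = as.integer(y)
  )
}

toy8 <- function() toy8_cohort()
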