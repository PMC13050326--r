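# Internal engine: everything here works on bare score/label vectors so that
# resampling loops avoid per-replicate data-frame overhead. User-facing
# wrappers in the other files validate inputs and return tibbles.

stop_validation <- function(msg, ...) {
  abort(msg, class = c("saroc_validation_error", "saroc_error"), ...)
}

stop_usage <- function(msg, ...) {
  abort(msg, class = c("saroc_usage_error", "saroc_error"), ...)
}

stop_io <- function(msg, ...) {
  abort(msg, class = c("saroc_io_error", "saroc_error"), ...)
}

cohort_fingerprint <- function(score, label) {
  rlang::hash(list(as.numeric(score), as.integer(label)))
}

# Candidate decision thresholds: ascending unique scores bracketed by a low
# sentinel (all cases called positive, same table as tau = min score) and a
# high sentinel (no case called positive).
.candidates <- function(s) {
  u <- sort(unique(s))
  c(u[1L] - 1, u, u[length(u)] + 1)
}

# Confusion statistics at every candidate threshold, via one sort and
# cumulative sums. Positive call is score >= tau; negative call is score < tau.
# ppv/npv are NA_real_ where the respective call set is empty (UNDEFINED).
.thresh_table <- function(s, y) {
  o <- order(s)
  ss <- s[o]
  yy <- y[o]
  n <- length(ss)
  new <- c(TRUE, ss[-1L] > ss[-n])
  grp <- cumsum(new)
  u <- ss[new]
  n_u <- length(u)
  pos_at_u <- as.integer(rowsum(yy, grp, reorder = FALSE))
  all_at_u <- tabulate(grp, nbins = n_u)
  neg_at_u <- all_at_u - pos_at_u
  npos <- sum(pos_at_u)
  nneg <- n - npos

  cum_pos <- cumsum(pos_at_u)
  cum_neg <- cumsum(neg_at_u)
  # positives with score >= candidate: low sentinel = all, u_j, high = none
  tp <- c(npos, npos - c(0L, cum_pos[-n_u]), 0L)
  fp <- c(nneg, nneg - c(0L, cum_neg[-n_u]), 0L)
  fn <- npos - tp
  tn <- nneg - fp
  tau <- c(u[1L] - 1, u, u[n_u] + 1)

  n_called_pos <- tp + fp
  n_called_neg <- tn + fn
  ppv <- ifelse(n_called_pos > 0, tp / n_called_pos, NA_real_)
  npv <- ifelse(n_called_neg > 0, tn / n_called_neg, NA_real_)
  tpr <- if (npos > 0) tp / npos else rep(NA_real_, length(tau))
  fpr <- if (nneg > 0) fp / nneg else rep(NA_real_, length(tau))

  list(
    tau = tau, tp = tp, fp = fp, tn = tn, fn = fn,
    tpr = tpr, fpr = fpr, ppv = ppv, npv = npv,
    n = n, npos = npos, nneg = nneg
  )
}

# Rank-statistic AUC with ties counted one half.
.auc <- function(s, y) {
  npos <- sum(y)
  nneg <- length(y) - npos
  r <- rank(s)
  (sum(r[y == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# Rule-in boundary: smallest candidate whose defined PPV meets alpha_plus
# (the attained infimum of the qualifying set). NA_real_ when no candidate
# qualifies (empty Rule-in Zone).
.rule_in <- function(tt, alpha_plus) {
  ok <- !is.na(tt$ppv) & tt$ppv >= alpha_plus
  if (!any(ok)) NA_real_ else tt$tau[which(ok)[1L]]
}

# Rule-out boundary: largest candidate whose defined NPV meets alpha_minus
# (the attained supremum). NA_real_ when none qualifies.
.rule_out <- function(tt, alpha_minus) {
  ok <- !is.na(tt$npv) & tt$npv >= alpha_minus
  if (!any(ok)) NA_real_ else tt$tau[max(which(ok))]
}

# Effective thresholds: empty Rule-in behaves as a threshold above every
# score (TPR = 0); empty Rule-out as at/below every score (FPR = 1).
.eff_plus <- function(tau_plus) if (is.na(tau_plus)) Inf else tau_plus
.eff_minus <- function(tau_minus) if (is.na(tau_minus)) -Inf else tau_minus

# Boundaries plus overlap resolution: if both are finite and tau_minus ends
# up above tau_plus (lenient targets), clip tau_minus down to tau_plus so
# the three zones remain a partition; rule-in keeps priority. The raw
# (unclipped) rule-out boundary is retained: the Gray Zone Area is defined
# from the attained sup/inf boundaries themselves, which keeps it exactly
# monotone in the symmetric safety level.
.boundaries <- function(tt, alpha_plus, alpha_minus, warn_clip = TRUE) {
  tau_plus <- .rule_in(tt, alpha_plus)
  tau_minus_raw <- .rule_out(tt, alpha_minus)
  tau_minus <- tau_minus_raw
  clipped <- FALSE
  if (!is.na(tau_plus) && !is.na(tau_minus) && tau_minus > tau_plus) {
    tau_minus <- tau_plus
    clipped <- TRUE
    if (warn_clip) {
      warn("Rule-out boundary exceeded the rule-in boundary; clipped tau_minus down to tau_plus.",
        class = "saroc_clipped_warning"
      )
    }
  }
  list(tau_plus = tau_plus, tau_minus = tau_minus,
       tau_minus_raw = tau_minus_raw, clipped = clipped)
}

# Zone of each score: rule_in iff s >= tau_plus, rule_out iff s < tau_minus,
# gray otherwise.
.zone_of <- function(s, tau_plus, tau_minus) {
  tp_eff <- .eff_plus(tau_plus)
  tm_eff <- .eff_minus(tau_minus)
  z <- rep("gray", length(s))
  z[s >= tp_eff] <- "rule_in"
  z[s < tm_eff & s < tp_eff] <- "rule_out"
  factor(z, levels = c("rule_out", "gray", "rule_in"))
}

# Interpolation-free confusion statistics at one arbitrary threshold.
.confusion <- function(s, y, tau) {
  pos_call <- s >= tau
  tp <- sum(pos_call & y == 1L)
  fp <- sum(pos_call & y == 0L)
  fn <- sum(y == 1L) - tp
  tn <- sum(y == 0L) - fp
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

.fpr_at <- function(s, y, tau) sum(y == 0L & s >= tau) / sum(y == 0L)
.tpr_at <- function(s, y, tau) sum(y == 1L & s >= tau) / sum(y == 1L)

# Gray Zone Area for resolved boundaries: FPR(tau_minus) * (1 - TPR(tau_plus)).
.gamma_area <- function(s, y, tau_plus, tau_minus) {
  .fpr_at(s, y, .eff_minus(tau_minus)) * (1 - .tpr_at(s, y, .eff_plus(tau_plus)))
}

# Symmetric-partition workload metrics used by the resampling loops.
.zone_metrics <- function(s, y, alpha_plus, alpha_minus = alpha_plus) {
  tt <- .thresh_table(s, y)
  b <- .boundaries(tt, alpha_plus, alpha_minus, warn_clip = FALSE)
  tp_eff <- .eff_plus(b$tau_plus)
  tm_eff <- .eff_minus(b$tau_minus)
  n <- length(s)
  n_rule_in <- sum(s >= tp_eff)
  rule_out <- s < tm_eff & s < tp_eff
  n_rule_out <- sum(rule_out)
  c(
    tau_plus = unname(b$tau_plus), tau_minus = unname(b$tau_minus),
    n_rule_in = n_rule_in, n_rule_out = n_rule_out,
    rule_out_tn = sum(rule_out & y == 0L),
    gray_fraction = (n - n_rule_in - n_rule_out) / n,
    gamma_area = .gamma_area(s, y, b$tau_plus, b$tau_minus_raw)
  )
}

# Preserve the caller's RNG stream across seeded operations.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}
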