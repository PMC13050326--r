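# Safe-Zone boundary search and three-zone partition.
#
# The Rule-in Safe Zone is {s >= tau_plus} where tau_plus is the attained
# infimum over candidate thresholds whose (defined) PPV meets alpha_plus;
# the Rule-out Safe Zone is {s < tau_minus} with tau_minus the attained
# supremum over candidates whose (defined) NPV meets alpha_minus; the Gray
# Zone is the remainder. Because the candidate grid is finite, the inf/sup
# are attained minima/maxima and the boundary predictive values meet their
# targets by construction.

.check_alpha <- function(alpha, name) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha > 1) {
    stop_usage(sprintf("`%s` must be a single number in (0, 1].", name))
  }
  alpha
}

#' Rule-in Safe Zone boundary
#'
#' The smallest candidate threshold whose defined PPV meets or exceeds
#' `alpha_plus`; scores at or above it form the Rule-in Safe Zone.
#'
#' @param cohort A cohort tibble with both classes present.
#' @param alpha_plus Rule-in safety level (minimum acceptable PPV), in
#'   `(0, 1]`.
#' @return The boundary threshold, or `NA_real_` when no candidate
#'   qualifies (empty Rule-in Zone).
#' @export
rule_in_boundary <- function(cohort, alpha_plus) {
  cohort <- check_cohort(cohort, require_both_classes = TRUE)
  .check_alpha(alpha_plus, "alpha_plus")
  .rule_in(.thresh_table(cohort$score, cohort$label), alpha_plus)
}

#' Rule-out Safe Zone boundary
#'
#' The largest candidate threshold whose defined NPV meets or exceeds
#' `alpha_minus`; scores strictly below it form the Rule-out Safe Zone.
#'
#' @param cohort A cohort tibble with both classes present.
#' @param alpha_minus Rule-out safety level (minimum acceptable NPV), in
#'   `(0, 1]`.
#' @return The boundary threshold, or `NA_real_` when no candidate
#'   qualifies (empty Rule-out Zone).
#' @export
rule_out_boundary <- function(cohort, alpha_minus) {
  cohort <- check_cohort(cohort, require_both_classes = TRUE)
  .check_alpha(alpha_minus, "alpha_minus")
  .rule_out(.thresh_table(cohort$score, cohort$label), alpha_minus)
}

#' Partition a cohort into Rule-in, Rule-out, and Gray Zones
#'
#' Derives both Safe-Zone boundaries under the given safety policy and
#' assigns every case to exactly one zone. If lenient targets make the two
#' zones overlap (`tau_minus > tau_plus`), `tau_minus` is clipped down to
#' `tau_plus` with a warning and the `clipped` flag set; rule-in retains
#' priority because escalation is the fail-safe direction.
#'
#' @param cohort A cohort tibble with both classes present.
#' @param alpha_plus Rule-in safety level (minimum acceptable PPV).
#' @param alpha_minus Rule-out safety level (minimum acceptable NPV);
#'   defaults to `alpha_plus` (the symmetric convention).
#' @return An `sa_partition` object; use [tidy()] for per-case zone
#'   assignments and [glance()] for the one-row summary (boundaries, zone
#'   counts, achieved PPV/NPV, Gray-Zone fraction and Gray Zone Area).
#' @examples
#' part <- make_partition(toy8_cohort(), alpha_plus = 1, alpha_minus = 1)
#' glance(part)
#' @export
make_partition <- function(cohort, alpha_plus, alpha_minus = alpha_plus) {
  cohort <- check_cohort(cohort, require_both_classes = TRUE)
  .check_alpha(alpha_plus, "alpha_plus")
  .check_alpha(alpha_minus, "alpha_minus")
  s <- cohort$score
  y <- cohort$label
  tt <- .thresh_table(s, y)
  b <- .boundaries(tt, alpha_plus, alpha_minus)
  zone <- .zone_of(s, b$tau_plus, b$tau_minus)

  tp_eff <- .eff_plus(b$tau_plus)
  tm_eff <- .eff_minus(b$tau_minus)
  cc_in <- .confusion(s, y, tp_eff)
  n_tn <- sum(y == 0L & s < tm_eff)
  n_fn <- sum(y == 1L & s < tm_eff)

  data <- cohort
  data$zone <- zone
  structure(
    list(
      data = data,
      alpha_plus = alpha_plus,
      alpha_minus = alpha_minus,
      tau_plus = b$tau_plus,
      tau_minus = b$tau_minus,
      tau_minus_raw = b$tau_minus_raw,
      rule_in_empty = is.na(b$tau_plus),
      rule_out_empty = is.na(b$tau_minus),
      clipped = b$clipped,
      achieved_ppv = if (cc_in[["tp"]] + cc_in[["fp"]] > 0) {
        cc_in[["tp"]] / (cc_in[["tp"]] + cc_in[["fp"]])
      } else {
        NA_real_
      },
      achieved_npv = if (n_tn + n_fn > 0) n_tn / (n_tn + n_fn) else NA_real_,
      fingerprint = cohort_fingerprint(s, y)
    ),
    class = "sa_partition"
  )
}

.as_boundaries <- function(x) {
  if (inherits(x, "sa_partition")) {
    list(tau_plus = x$tau_plus, tau_minus = x$tau_minus_raw %||% x$tau_minus,
         fingerprint = x$fingerprint)
  } else if (is.list(x) && all(c("tau_plus", "tau_minus") %in% names(x))) {
    list(tau_plus = x$tau_plus, tau_minus = x$tau_minus_raw %||% x$tau_minus,
         fingerprint = x$fingerprint %||% NULL)
  } else {
    stop_usage("Expected an sa_partition or a list with tau_plus/tau_minus.")
  }
}

#' @export
print.sa_partition <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<sa_partition>  alpha+ = %.3g, alpha- = %.3g\n", x$alpha_plus, x$alpha_minus
  ))
  cat(sprintf(
    "  tau+ = %s, tau- = %s%s\n",
    if (x$rule_in_empty) "EMPTY" else format(x$tau_plus),
    if (x$rule_out_empty) "EMPTY" else format(x$tau_minus),
    if (x$clipped) " (clipped)" else ""
  ))
  cat(sprintf(
    "  zones: rule_out %d | gray %d | rule_in %d   gray_fraction = %.4g, gamma_area = %.4g\n",
    g$n_rule_out, g$n_gray, g$n_rule_in, g$gray_fraction, g$gamma_area
  ))
  invisible(x)
}

#' @describeIn make_partition Per-case tibble of zone assignments.
#' @param x An `sa_partition` object.
#' @param ... Unused.
#' @export
tidy.sa_partition <- function(x, ...) {
  x$data
}

#' @describeIn make_partition One-row summary tibble.
#' @export
glance.sa_partition <- function(x, ...) {
  z <- x$data$zone
  s <- x$data$score
  y <- x$data$label
  tibble::tibble(
    alpha_plus = x$alpha_plus,
    alpha_minus = x$alpha_minus,
    tau_plus = x$tau_plus,
    tau_minus = x$tau_minus,
    clipped = x$clipped,
    n = length(z),
    n_rule_in = sum(z == "rule_in"),
    n_gray = sum(z == "gray"),
    n_rule_out = sum(z == "rule_out"),
    gray_fraction = mean(z == "gray"),
    gamma_area = .gamma_area(s, y, x$tau_plus, x$tau_minus_raw %||% x$tau_minus),
    achieved_ppv = x$achieved_ppv,
    achieved_npv = x$achieved_npv
  )
}

#' Safety Profile: workload across a grid of safety levels
#'
#' For each safety level on the grid, derives the corresponding partition
#' and records its boundaries, Gray-Zone fraction and Gray Zone Area. The
#' default (symmetric) mode sets `alpha_plus = alpha_minus = alpha`,
#' matching the standard configuration used for Safety Profile Curves; the
#' fixed modes hold one side constant while the grid varies the other.
#'
#' @param cohort A cohort tibble with both classes present.
#' @param alphas Grid of safety levels in `(0, 1]`; default 0.50 to 1.00 in
#'   steps of 0.005 (101 levels).
#' @param mode `"symmetric"` (default), `"fixed_alpha_minus"` or
#'   `"fixed_alpha_plus"`.
#' @param fixed The fixed safety level for the non-symmetric modes.
#' @return An `sa_profile` tibble with columns `alpha`, `alpha_plus`,
#'   `alpha_minus`, `tau_minus`, `tau_plus`, `clipped`, `gray_fraction`,
#'   `gamma_area`, ordered by `alpha`.
#' @export
safety_profile <- function(cohort,
                           alphas = seq(0.5, 1, by = 0.005),
                           mode = c("symmetric", "fixed_alpha_minus", "fixed_alpha_plus"),
                           fixed = NULL) {
  cohort <- check_cohort(cohort, require_both_classes = TRUE)
  mode <- match.arg(mode)
  if (length(alphas) == 0) stop_usage("`alphas` must be a nonempty grid.")
  purrr::walk(alphas, .check_alpha, name = "alphas")
  if (mode != "symmetric") {
    if (is.null(fixed)) stop_usage("`fixed` is required for the fixed modes.")
    .check_alpha(fixed, "fixed")
  }
  alphas <- sort(alphas)
  s <- cohort$score
  y <- cohort$label
  tt <- .thresh_table(s, y)
  n <- length(s)

  rows <- purrr::map(alphas, function(a) {
    ap <- switch(mode, symmetric = a, fixed_alpha_minus = a, fixed_alpha_plus = fixed)
    am <- switch(mode, symmetric = a, fixed_alpha_minus = fixed, fixed_alpha_plus = a)
    b <- .boundaries(tt, ap, am, warn_clip = FALSE)
    tp_eff <- .eff_plus(b$tau_plus)
    tm_eff <- .eff_minus(b$tau_minus)
    n_in <- sum(s >= tp_eff)
    n_out <- sum(s < tm_eff)
    tibble::tibble(
      alpha = a, alpha_plus = ap, alpha_minus = am,
      tau_minus = b$tau_minus, tau_plus = b$tau_plus, clipped = b$clipped,
      gray_fraction = (n - n_in - n_out) / n,
      gamma_area = .gamma_area(s, y, b$tau_plus, b$tau_minus_raw)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sa_profile", class(out))
  attr(out, "mode") <- mode
  attr(out, "fixed") <- fixed
  attr(out, "fingerprint") <- cohort_fingerprint(s, y)
  out
}
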