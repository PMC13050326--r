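# Synthetic score-cohort generation: pairs of Beta distributions over
# [0, 1] emulating the class-conditional score distributions of binary
# clinical classifiers, with analytic AUC and one-parameter calibration
# families so scenarios can be pinned to a target AUC.

#' Define a Beta-distribution score scenario
#'
#' Negative-class scores are drawn from `Beta(a0, b0)` and positive-class
#' scores from `Beta(a1, b1)`; draws lie in `[0, 1]` by construction.
#'
#' @param a0,b0 Positive shape parameters of the negative-class distribution.
#' @param a1,b1 Positive shape parameters of the positive-class distribution.
#' @param n_neg,n_pos Class sample sizes (defaults 5000 + 5000).
#' @param seed Integer seed used by [sample_scenario()].
#' @param name Optional scenario name.
#' @return An `sa_scenario` list.
#' @export
beta_scenario <- function(a0, b0, a1, b1, n_neg = 5000, n_pos = 5000,
                          seed = 1, name = NULL) {
  shapes <- c(a0 = a0, b0 = b0, a1 = a1, b1 = b1)
  if (!all(is.finite(shapes)) || any(shapes <= 0)) {
    stop_validation("All Beta shape parameters must be positive and finite.")
  }
  if (n_neg < 1 || n_pos < 1) {
    stop_validation("Class sizes must be positive integers.")
  }
  structure(
    list(a0 = a0, b0 = b0, a1 = a1, b1 = b1,
         n_neg = as.integer(n_neg), n_pos = as.integer(n_pos),
         seed = as.integer(seed), name = name),
    class = "sa_scenario"
  )
}

#' @export
print.sa_scenario <- function(x, ...) {
  cat(sprintf(
    "<sa_scenario>%s neg ~ Beta(%.4g, %.4g), pos ~ Beta(%.4g, %.4g), n = %d + %d, seed = %d\n",
    if (is.null(x$name)) "" else paste0(" ", x$name, ":"),
    x$a0, x$b0, x$a1, x$b1, x$n_neg, x$n_pos, x$seed
  ))
  invisible(x)
}

#' Sample a scored cohort from a Beta scenario
#'
#' @param scenario An [beta_scenario()] (or [scenario_preset()]) object.
#' @return A cohort tibble with auto-assigned case ids (`neg_...`,
#'   `pos_...`); deterministic given the scenario seed. Tied sampled
#'   scores, if any, are kept.
#' @export
sample_scenario <- function(scenario) {
  if (!inherits(scenario, "sa_scenario")) {
    stop_usage("`scenario` must be created by beta_scenario() or scenario_preset().")
  }
  .with_seed(scenario$seed, {
    neg <- rbeta(scenario$n_neg, scenario$a0, scenario$b0)
    pos <- rbeta(scenario$n_pos, scenario$a1, scenario$b1)
    tibble::tibble(
      case_id = c(
        sprintf("neg_%0*d", nchar(scenario$n_neg), seq_len(scenario$n_neg)),
        sprintf("pos_%0*d", nchar(scenario$n_pos), seq_len(scenario$n_pos))
      ),
      score = c(neg, pos),
      label = c(rep(0L, scenario$n_neg), rep(1L, scenario$n_pos))
    )
  })
}

#' Analytic AUC of a Beta-vs-Beta scenario
#'
#' `P(X1 > X0)` for independent `X0 ~ Beta(a0, b0)`, `X1 ~ Beta(a1, b1)`,
#' by numerical integration of `f1(x) * F0(x)` over `[0, 1]` to absolute
#' tolerance 1e-6 (ties have probability zero for continuous scores).
#'
#' @inheritParams beta_scenario
#' @return A double in `[0, 1]`.
#' @export
analytic_auc <- function(a0, b0, a1, b1) {
  shapes <- c(a0, b0, a1, b1)
  if (!all(is.finite(shapes)) || any(shapes <= 0)) {
    stop_validation("All Beta shape parameters must be positive and finite.")
  }
  res <- tryCatch(
    integrate(function(x) dbeta(x, a1, b1) * pbeta(x, a0, b0), 0, 1,
              abs.tol = 1e-8, rel.tol = 1e-8, subdivisions = 500L),
    error = function(e) stop_validation(paste0("AUC integration failed: ", conditionMessage(e)))
  )
  if (res$abs.error > 1e-6) {
    stop_validation("AUC integration did not reach the required tolerance.")
  }
  min(max(res$value, 0), 1)
}

# Calibration families. Each maps a single free parameter to a Beta pair;
# the free parameter is root-found so the analytic AUC hits the target.
.family_shapes <- function(family, par, width = NULL) {
  switch(family,
    "symmetric-skew" = list(a0 = 1, b0 = par, a1 = par, b1 = 1),
    "location-shift" = {
      nu <- 10
      m0 <- 0.5 - par / 2
      m1 <- 0.5 + par / 2
      list(a0 = nu * m0, b0 = nu * (1 - m0), a1 = nu * m1, b1 = nu * (1 - m1))
    },
    "overlap-width" = {
      nu <- 2 / width^2
      m0 <- 0.5 - par / 2
      m1 <- 0.5 + par / 2
      list(a0 = nu * m0, b0 = nu * (1 - m0), a1 = nu * m1, b1 = nu * (1 - m1))
    },
    "rule-in-skew" = list(a0 = 1.5, b0 = 3, a1 = par, b1 = 1),
    "rule-out-skew" = list(a0 = 1, b0 = par, a1 = 3, b1 = 1.5),
    "narrow-separation" = {
      # tightly concentrated positives (concentration 50, free mean) against
      # negatives massed at the bottom of the score range; the outer tails
      # vanish quickly, so the Gray Zone at stringent safety levels stays
      # small even though the AUC is held down by the negatives' upper tail
      nu <- 50
      list(a0 = 0.4, b0 = 2.2, a1 = nu * par, b1 = nu * (1 - par))
    }
  )
}

.family_range <- function(family) {
  switch(family,
    "symmetric-skew" = c(1 + 1e-6, 400),
    "location-shift" = c(1e-6, 0.98),
    "overlap-width" = c(1e-6, 0.98),
    "rule-in-skew" = c(1e-4, 400),
    "rule-out-skew" = c(1e-4, 400),
    "narrow-separation" = c(0.4, 0.99)
  )
}

#' Calibrate a Beta scenario to a target AUC
#'
#' One-dimensional root-find on the free parameter of a calibration family
#' so that the analytic AUC matches `target_auc` to within 1e-4:
#'
#' * `symmetric-skew`: `Beta(1, k)` vs `Beta(k, 1)`, free `k` — both
#'   classes pile up at their own end of the score range.
#' * `location-shift`: mirrored means `0.5 +/- delta/2` at fixed
#'   concentration 10, free separation `delta`.
#' * `overlap-width`: as location-shift but with the concentration set by
#'   `width` (dispersion scale; larger is wider/noisier), free `delta`.
#' * `rule-in-skew`: positives peaked near 1 (`Beta(k, 1)`, free `k`)
#'   against a fixed broad low-scoring negative class — a model built for
#'   confident escalation.
#' * `rule-out-skew`: negatives peaked near 0 (`Beta(1, k)`, free `k`)
#'   against a fixed broad high-scoring positive class — a model built for
#'   confident exclusion.
#' * `narrow-separation`: a tightly concentrated positive class
#'   (concentration 50, free mean) against negatives massed at the bottom
#'   of the score range; the outer tails vanish quickly, so stringent
#'   safety levels leave only a small Gray Zone.
#'
#' @param target_auc Target AUC, strictly inside `(0.5, 1)`.
#' @param family Calibration family (see above).
#' @param width Dispersion scale for the `overlap-width` family.
#' @param n_neg,n_pos,seed,name Passed to [beta_scenario()].
#' @return A calibrated `sa_scenario`.
#' @export
calibrate_to_auc <- function(target_auc,
                             family = c("symmetric-skew", "location-shift",
                                        "overlap-width", "rule-in-skew",
                                        "rule-out-skew", "narrow-separation"),
                             width = NULL, n_neg = 5000, n_pos = 5000,
                             seed = 1, name = NULL) {
  family <- match.arg(family)
  if (!is.numeric(target_auc) || length(target_auc) != 1 ||
      target_auc <= 0.5 || target_auc >= 1) {
    stop_usage("`target_auc` must lie strictly inside (0.5, 1).")
  }
  if (family == "overlap-width") {
    if (is.null(width) || width <= 0 || width >= 1.5) {
      stop_usage("`width` in (0, 1.5) is required for the overlap-width family.")
    }
  }
  f <- function(par) {
    sh <- .family_shapes(family, par, width)
    analytic_auc(sh$a0, sh$b0, sh$a1, sh$b1) - target_auc
  }
  rng <- .family_range(family)
  lo <- f(rng[1])
  hi <- f(rng[2])
  if (sign(lo) == sign(hi)) {
    stop_validation(sprintf(
      "Target AUC %.4g is unattainable within the '%s' family.", target_auc, family
    ))
  }
  root <- uniroot(f, rng, tol = 1e-10)
  sh <- .family_shapes(family, root$root, width)
  achieved <- analytic_auc(sh$a0, sh$b0, sh$a1, sh$b1)
  if (abs(achieved - target_auc) > 1e-4) {
    stop_validation("Calibration did not converge to the target AUC within 1e-4.")
  }
  out <- beta_scenario(sh$a0, sh$b0, sh$a1, sh$b1, n_neg = n_neg,
                       n_pos = n_pos, seed = seed, name = name)
  out$family <- family
  out$free_parameter <- root$root
  out$width <- width
  out$target_auc <- target_auc
  out$analytic_auc <- achieved
  out
}

#' Named scenario presets
#'
#' Four calibrated reference scenarios spanning qualitatively different
#' operational safety profiles:
#'
#' * `rule_in_skew` — modest AUC 0.768 with positives sharply peaked at
#'   high scores: a strong Rule-in Safe Zone.
#' * `rule_out_skew` — similar AUC 0.780 skewed toward negatives: an
#'   expansive Rule-out Safe Zone.
#' * `wide_overlap` — AUC 0.960 from wide, overlapping distributions:
#'   large Gray Zone at stringent safety levels.
#' * `narrow_separation` — the same AUC 0.960 from narrow, well-separated
#'   distributions: much smaller Gray Zone.
#'
#' @param name Preset name.
#' @param n_neg,n_pos,seed Passed to the scenario.
#' @return A calibrated `sa_scenario`.
#' @export
scenario_preset <- function(name = c("rule_in_skew", "rule_out_skew",
                                     "wide_overlap", "narrow_separation"),
                            n_neg = 5000, n_pos = 5000, seed = 1) {
  name <- match.arg(name)
  switch(name,
    rule_in_skew = calibrate_to_auc(0.768, family = "rule-in-skew",
                                    n_neg = n_neg, n_pos = n_pos,
                                    seed = seed, name = name),
    rule_out_skew = calibrate_to_auc(0.780, family = "rule-out-skew",
                                     n_neg = n_neg, n_pos = n_pos,
                                     seed = seed, name = name),
    wide_overlap = calibrate_to_auc(0.960, family = "overlap-width",
                                    width = 0.7, n_neg = n_neg,
                                    n_pos = n_pos, seed = seed, name = name),
    narrow_separation = calibrate_to_auc(0.960, family = "narrow-separation",
                                         n_neg = n_neg, n_pos = n_pos,
                                         seed = seed, name = name)
  )
}

#' Eight-case worked example cohort
#'
#' A deliberately small cohort (4 positives scoring 0.9/0.8/0.7/0.4, 4
#' negatives scoring 0.6/0.3/0.2/0.1) whose zone boundaries, AUC and
#' workload metrics can all be verified by hand; used throughout the
#' documentation and tests.
#'
#' @return A cohort tibble of eight cases.
#' @export
toy8_cohort <- function() {
  tibble::tibble(
    case_id = c("p1", "p2", "p3", "p4", "n1", "n2", "n3", "n4"),
    score = c(0.9, 0.8, 0.7, 0.4, 0.6, 0.3, 0.2, 0.1),
    label = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)
  )
}
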