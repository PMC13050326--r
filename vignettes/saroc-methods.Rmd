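---
title: "Methods: safety zones, workload metrics, and operating policies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: safety zones, workload metrics, and operating policies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saroc)
```

## The decision problem

A binary classifier scores each case with *s* ∈ [0, 1]. Conventional
evaluation summarizes ranking quality (AUC), but deployment requires a
different object: the set of scores at which an *autonomous* action —
escalating a case, or de-prioritizing it — meets a stated reliability
target. `saroc` formalizes this with two clinician-set levels: α⁺, the
minimum PPV acceptable for an autonomous positive call, and α⁻, the minimum
NPV acceptable for an autonomous negative call. The package's convention
throughout is that a positive call at threshold τ is `score >= tau` (closed
at τ) and a negative call is `score < tau`.

Both Safe-Zone boundaries come from an exhaustive scan of the *candidate
thresholds*: the cohort's unique scores, bracketed by a sentinel below the
minimum (every case called positive) and one above the maximum (none
called). Every achievable confusion table appears on this grid, so the
infimum and supremum that define the boundaries are attained as ordinary
minima and maxima — no real-line search and no score binning:

* rule-in boundary τ⁺ — the smallest candidate whose PPV is defined and
  ≥ α⁺; the Rule-in Safe Zone is `score >= tau_plus`;
* rule-out boundary τ⁻ — the largest candidate whose NPV is defined and
  ≥ α⁻; the Rule-out Safe Zone is `score < tau_minus`;
* Gray Zone — the remainder, designated for human review.

Thresholds where PPV or NPV has an empty denominator are *undefined*
(`NA`), not zero or one, and never qualify: a vacuous reliability claim
must not open a Safe Zone. Because the boundary is itself a qualifying
threshold, the PPV over the Rule-in Zone and the NPV over the Rule-out Zone
meet their targets whenever the zone is nonempty — an **in-sample guarantee
by construction**, not a generalization claim (see Limitations).

PPV is non-monotone in τ, so the qualifying set can have gaps above its
infimum. Following the boundary definitions literally, the zone extends
down to the infimum regardless of interior dips; the achieved zone-level
PPV/NPV (which the construction guarantees) is reported alongside, since
zone-level reliability is the operative clinical contract.

## Degenerate and overlapping configurations

Two edge cases need explicit conventions:

* **Empty zones.** If no candidate qualifies, the boundary is reported as
  empty (`NA`); an empty Rule-in Zone behaves as a threshold above every
  score (TPR = 0) and an empty Rule-out Zone as one at/below every score
  (FPR = 1). The workload metrics then degrade gracefully: with nothing
  automatable, the Gray Zone Area is exactly 1.
* **Overlap under lenient targets.** With small α the two zones can
  overlap (τ⁻ > τ⁺). The per-case assignment must remain a partition, so
  τ⁻ is clipped down to τ⁺, the `clipped` flag is set, and a warning is
  raised; rule-in retains priority because escalation is the fail-safe
  direction.

## Workload metrics

Two complementary costs of indecision are computed. The **Gray-Zone
fraction** is simply the share of cases assigned to the Gray Zone. The
**Gray Zone Area**,

$$\Gamma_{\mathrm{Area}} = \mathrm{FPR}(\tau^-)\,\bigl(1 - \mathrm{TPR}(\tau^+)\bigr),$$

is the rectangle the two boundary operating points cut out of the top-left
corner of ROC space. Γ_Area is always evaluated at the *attained* boundary
thresholds — in the overlap case, the unclipped τ⁻. This choice matters:
the raw boundaries are monotone in their targets (the qualifying sets
shrink as α grows), so Γ_Area evaluated there is exactly non-decreasing in
the symmetric safety level, whereas evaluating it at the clipped boundary
would make it dip in the overlap regime. The per-case partition uses the
clipped boundary; the area metric uses the raw one; both are stored on the
partition object.

The **Safety Profile** (`safety_profile()`) tabulates both metrics over a
grid of safety levels, by default 0.50–1.00 in steps of 0.005 (101 levels)
with α⁺ = α⁻ — the symmetric convention used for all profile displays; the
asymmetric modes hold one side fixed.

## Operating policies

A deployment policy is a resolved pair (τ⁻, τ⁺) with its achieved
reliabilities and zone counts. Two derivation paradigms are provided.

**Constraints (two of three).** The governing parameters are rule-in
reliability α⁺, rule-out reliability α⁻, and workload p₉ (the Gray-Zone
fraction). Fixing any two determines the third. With both α given, the
partition follows and p₉ is reported. With one α and a workload budget, the
free boundary is chosen to *maximize the achieved reliability on the free
side* (NPV for the rule-out boundary, PPV for the rule-in boundary) among
candidates that respect contiguity (τ⁻ ≤ τ⁺) and the budget, with ties
broken toward the smaller Gray Zone. Because the candidate grid is
discrete, the attained value *is* the best achievable target — searching an
α-grid would only add resolution artifacts. An unmeetable reliability
target yields an empty zone (this is how a "no false negatives tolerated"
mandate can legitimately eliminate the rule-out side entirely); the policy
object carries a feasibility flag rather than raising.

**Utility maximization.** Given finite per-case utilities for the five
dispositions (TP/FP in rule-in, TN/FN in rule-out, Gray deferral), the
optimizer finds the exact argmax of the total utility over all candidate
pairs τ⁻ ≤ τ⁺. Prefix-summed class counts make each pair O(1), and the
inner loop is vectorized, so the quadratic search stays desk-scale at
cohort sizes in the tens of thousands. Ties are resolved deterministically:
fewest errors (n_FP + n_FN), then fewest deferrals, then the
lexicographically smallest (τ⁻, τ⁺) — determinism is required for
reproducible policies and for exact agreement with the brute-force
enumeration (`enumerate_policies()`, capped at 5,000 cases by default)
that serves as its oracle in the tests.

The Youden threshold (reported on SA-ROC plots) breaks its own ties — J is
piecewise constant — toward higher TPR and then lower τ, favoring
sensitivity as appropriate in screening.

## Resampling

* **Percentile bootstrap** (`bootstrap_interval()`): B = 2000 resamples
  with replacement by default; the statistic (AUC, Γ_Area, Gray-Zone
  fraction, or ruled-out true-negative count) is recomputed on every
  resample with the zone boundaries *re-derived inside the replicate*
  (boundary uncertainty is usually the point; freezing them is available
  as a flag). The interval is the 2.5th/97.5th percentile pair (default
  `quantile()` type). Resamples that lose a class are rejected and
  redrawn, keeping B effective replicates; the count is reported.
* **Prevalence shift** (`prevalence_sweep()`): deployment prevalence is
  emulated by holding the complete negative cohort fixed — maximizing the
  effective reference sample — and resampling positives with replacement
  to `round(n_neg · p/(1−p))` (round-half-to-even, R's `round()`), so the
  realized prevalence is within 1/n of the target by construction.
* **Paired two-model comparison** (`paired_model_difference()`): for two
  models scoring the same cases, the difference in ruled-out true
  negatives at α⁻ is bootstrapped at the *case* level, both models
  resampled on the same indices and both boundaries re-derived per
  replicate. The pairing scheme is a documented interpretation; the
  statistic itself is fixed by the zone definitions.

RNG contract: every stochastic operation takes an explicit seed, uses one
R Mersenne-Twister stream started with `set.seed(seed)`, consumes draws
sequentially (a rejected resample consumes its draw), restores the caller's
RNG state, and echoes the seed in its result. Identical seeds give
bit-identical output, and the recipe is simple enough to reimplement
independently — one of the tests does exactly that.

## The synthetic-data generator

`sample_scenario()` draws class-conditional scores from a pair of Beta
distributions — negatives from Beta(a₀, b₀), positives from Beta(a₁, b₁) —
with 5,000 cases per class by default. This emulates the one feature of
real score data that drives operational safety: the *shape* of the two
score distributions, especially their outer tails. `analytic_auc()`
integrates `f₁·F₀` (absolute tolerance 10⁻⁶) so scenarios can be pinned to
a target AUC by a one-dimensional root-find (`calibrate_to_auc()`,
tolerance 10⁻⁴ on the achieved AUC).

Because the shape pair is the free object, calibration is organized into
one-parameter families: `symmetric-skew` (Beta(1,k) vs Beta(k,1)),
`location-shift` (mirrored means at fixed concentration 10),
`overlap-width` (as location-shift with the concentration set by a
dispersion scale), the one-sided `rule-in-skew`/`rule-out-skew` (one class
peaked against a fixed broad opponent), and `narrow-separation` (tightly
concentrated positives, concentration 50 with free mean, against negatives
massed at the bottom). Four named presets ship: `rule_in_skew` (AUC 0.768,
strong rule-in side), `rule_out_skew` (AUC 0.780, strong rule-out side),
and the matched pair `wide_overlap` / `narrow_separation`, both calibrated
to AUC 0.960 yet with very different Gray Zones at stringent safety levels.

The matched pair deserves a note. Numerical exploration during design
showed that for *mirrored* smooth Beta pairs at fixed AUC, Γ_Area at
α = 1 is nearly invariant to concentration: thinning the outer tails forces
the calibration to broaden the middles, and the two effects cancel. A
genuinely small Gray Zone at maximal stringency requires asymmetric
outer-tail structure — tails that vanish quickly on the side that matters —
which is what the `narrow-separation` family provides. The contrast between
the presets (wide ≈ 0.54–0.80 vs narrow ≈ 0.12–0.18 across seeds at
5,000 + 5,000) is therefore a property of the shapes, not of a tuned
constant.

What the generator does *not* emulate: miscalibration patterns of real
CNNs (score heaping, vendor-specific rounding), case-mix covariates,
reader-AI correlation, or inter-site drift. Tests passing on Beta cohorts
demonstrate the correctness of the zone machinery and the qualitative
shape-dependence of operational safety; they do not validate any specific
clinical model.

## Numerical choices

* Reliability comparisons are exact `>=` on double-precision count ratios;
  no tolerance is injected, so a target of 0.8 is met by 4/5 exactly.
* Sentinels are `min(score) − 1` and `max(score) + 1`; empty boundaries
  are `NA` and act as ±∞ in zone membership.
* Scores exactly 0 or 1 are legal (closed interval); duplicate sampled
  scores are kept — ties are exercised throughout the tests.
* AUC is the rank statistic with ties counted ½, which equals trapezoidal
  integration of the empirical ROC (asserted to 10⁻¹² in tests).
* Cohort fingerprints (a hash of scores and labels) prevent accidentally
  evaluating boundaries against a different cohort.

## Problem sizes used in the test suite

Oracle equivalence of the boundary search runs on 1,000 random cohorts
(n ≤ 50, with and without ties, mixed prevalences); monotonicity on 200
cohorts over the 101-level default grid; the utility optimizer against
full enumeration on 500 random cohort/utility instances (n ≤ 60); the
matched-AUC ordering over 20 seeds at 5,000 + 5,000; bootstrap
reproducibility at B = 2,000 on a 1,000-case, 40%-prevalence cohort; the
prevalence sweep with 600 fixed negatives at targets 1–40%. These sizes
give each property thousands of independent chances to fail while keeping
the default suite fast.

## Limitations

* All reliability guarantees are **in-sample**: the zones meet their
  targets on the cohort they were derived from. Out-of-sample coverage
  (conformal-style calibration/test splitting) is intentionally out of
  scope.
* At α near 1, boundaries depend on the sparse extremes of the score
  distributions; bootstrap intervals quantify but cannot remove this
  instability, and Γ_Area estimates there should be read accordingly.
* PPV/NPV-based zones are prevalence-dependent by design; the prevalence
  sweep explores this under the fixed-score-distribution assumption, which
  itself can fail under case-mix shift.
* Utilities are per-case constants; covariate-dependent utilities are not
  supported.
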