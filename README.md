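# saroc — safety-aware ROC analysis for clinical risk scores

High discrimination does not tell a clinician *when* it is safe to act on a
model's output. `saroc` addresses that question for any binary classifier
that emits a continuous risk score in [0, 1] (a mammography CNN, a sepsis
alert, a lab-triage model): given clinician-set reliability targets, it
splits the score range into the region where an automated positive call is
trustworthy, the region where an automated negative call is trustworthy,
and the remainder that must go to a human. It is written for biostatisticians
and clinical-AI evaluation teams working with per-case score/label tables.

## The model

Let each case *i* have a score *s*ᵢ ∈ [0, 1] and a true class *y*ᵢ ∈ {0, 1}.
A positive call at threshold τ is *s*ᵢ ≥ τ. Two reliability targets are set:
**α⁺**, the minimum acceptable PPV for autonomous escalation, and **α⁻**, the
minimum acceptable NPV for autonomous de-prioritization. Scanning all
candidate thresholds (the unique observed scores plus two sentinels):

* **Rule-in Safe Zone**: scores at or above τ⁺ = inf { τ : PPV(τ) ≥ α⁺ };
* **Rule-out Safe Zone**: scores strictly below τ⁻ = sup { τ : NPV(τ) ≥ α⁻ };
* **Gray Zone**: everything in between — mandated human review.

The cost of indecision is summarized two ways: the Gray-Zone fraction of the
cohort, and the **Gray Zone Area**

Γ_Area = FPR(τ⁻) × (1 − TPR(τ⁺)),

the rectangle the Gray Zone cuts out of the top-left corner of ROC space.
Operating policies can be derived either from constraints (fix any two of
α⁺, α⁻ and the workload budget *p*₉; the third is optimized) or by exact
maximization of a per-case utility

U_total = n_TP·U_TP + n_TN·U_TN + n_FP·U_FP + n_FN·U_FN + n_Gray·U_Gray

over all threshold pairs τ⁻ ≤ τ⁺. Percentile bootstrap and prevalence-shift
resampling quantify the stability of all of these; a Beta-distribution
cohort simulator provides calibrated synthetic score distributions.

## Worked example

```r
library(saroc)

cohort <- toy8_cohort()   # 4 positives (0.9 0.8 0.7 0.4), 4 negatives (0.6 0.3 0.2 0.1)
part <- make_partition(cohort, alpha_plus = 1, alpha_minus = 1)
part
#> <sa_partition>  alpha+ = 1, alpha- = 1
#>   tau+ = 0.7, tau- = 0.4
#>   zones: rule_out 3 | gray 2 | rule_in 3   gray_fraction = 0.25, gamma_area = 0.0625
```

At 100% reliability both ways, every score ≥ 0.7 may be escalated
autonomously (all three such cases are true positives), every score < 0.4
may be de-prioritized (all three are true negatives), and the two
mid-range cases (0.4 and 0.6) — 25% of the cohort — must be read by a
human. Γ_Area = FPR(0.4) × (1 − TPR(0.7)) = 0.25 × 0.25 = 0.0625.

Deriving a policy from a rule-out mandate plus a workload budget:

```r
solve_constraints(cohort, alpha_minus = 1, p_g_max = 0.25)
#> <sa_policy>  pathway C
#>   tau+ = 0.7, tau- = 0.4   achieved PPV = 1, NPV = 1
#>   counts: TP 3 FP 0 | gray 2 | TN 3 FN 0   p_g = 0.25
```

and bootstrapping the Gray Zone Area of a simulated 1000-case cohort whose
score distributions are calibrated to AUC 0.960:

```r
scn <- scenario_preset("wide_overlap", n_neg = 500, n_pos = 500, seed = 1)
bootstrap_interval(sample_scenario(scn), "gamma_area", alpha = 1, B = 500, seed = 2)
#>    statistic alpha    point     lower     upper   B seed n_redrawn
#> 1 gamma_area     1 0.307944 0.2096483 0.3342651 500    2         0
```

`plot_saroc()`, `plot_safety_profile()` and `plot_two_model_grid()` draw the
zone-colored ROC curve, the workload-versus-stringency profile, and the
paired two-model comparison; `render_*()` variants write figure files with
JSON sidecars carrying the exact plotted numbers. A small CLI wrapper
(`inst/cli/saroc.R`) exposes `zones`, `profile`, `policy`, `compare` and
`simulate` subcommands over cohort CSV files.

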