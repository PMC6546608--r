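---
title: "Methods: pre/post-controlled meta-analysis with ppcmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pre/post-controlled meta-analysis with ppcmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppcmeta)
```

## The problem

Trials of mindfulness-based interventions (MBIs) in children and
adolescents are typically small randomized controlled trials reporting,
per arm, the pre-intervention and post-intervention mean and SD of each
outcome instrument. Instruments are heterogeneous, so synthesis proceeds
in three steps: standardize each measure into a pre-post-controlled
effect size, average measures of the same outcome category within a
study, and pool the study-level composites per category with a
random-effects model. `ppcmeta` implements that pipeline, together with
funnel-based publication-bias diagnostics, single-moderator
meta-regressions, and a Cochrane-style risk-of-bias composite, all
driven by a plain three-CSV extraction format.

## Unit of analysis

A *comparison* is one (MBI arm, control arm) pair. Multi-arm trials —
one MBI arm against two control conditions of different types, or two
MBI variants against one control — enter as multiple comparisons sharing
an arm, and each comparison is treated as an independent pooled unit.
This matches how such trials appear in published control-type subgroup
tables (the same study contributes to two subgroup rows), keeps the
bookkeeping transparent, and is the reason degrees of freedom follow the
comparison-composite count rather than the study count. The shared-arm
dependency is documented, not modelled; participant totals de-duplicate
shared arms so nobody is counted twice within a row. Robust-variance or
multivariate treatment of the dependency is out of scope.

## Effect sizes

For each measure, `compute_ppc_d()` forms the change-score difference
divided by the pooled *pretest* SD. Pooling only pretest SDs keeps the
denominator free of any intervention effect on variability; the pooling
uses Bessel (n−1) weights, the standard reading when no explicit formula
is given in primary reports. Lower-is-better instruments (symptom
scales) have their sign flipped at this stage, so a positive d always
favours the MBI. Cohen's d is the default; the Hedges small-sample
factor `J = 1 − 3/(4(n1+n2−2)−1)` is an opt-in flag
(`es_config(hedges_correction = TRUE)`), since most primary syntheses of
this literature report uncorrected d.

Summary-statistic designs never report the within-arm pre/post
correlation, yet the change-score variance needs it:

`v = 2(1 − ρ)(1/n1 + 1/n2) + d²/(2(n1+n2))`.

We default `rho_prepost = 0.5` — the conventional midpoint for
psychological self-report measures, and the value at which `v` coincides
with the familiar two-group posttest-only variance — and expose it in
`es_config()` because pooled weights are sensitive to it. Sensitivity
analysis at 0.3 and 0.7 is cheap and recommended.

### Category composites

When a study assesses a category with m instruments, the composite is
the unweighted mean of the m d's. Its variance is
`(1/m²) Σᵢⱼ ρᵢⱼ √(vᵢvⱼ)` with `rho_measures` on the off-diagonal. We
default `rho_measures = 1`: under perfect correlation averaging gives no
precision gain, so the composite variance is never understated. This is
deliberately conservative — if the instruments were really independent
the truth would be up to m times smaller — and it propagates into
slightly conservative pooled CIs and downward-shaded heterogeneity
estimates whenever real instruments are less than perfectly correlated.

## Pooling and heterogeneity

`pool_random_effects()` uses DerSimonian–Laird (method-of-moments) τ² by
default because it is the default of the commercial software most
published syntheses in this area used; REML is available via
`es_config(tau2_method = "REML")`, implemented by profile optimization
of the restricted likelihood (inner tolerance 1e-10, with an explicit
boundary check at τ² = 0). Inference is normal (z) with 95% CIs at
±1.959964·se; no Knapp–Hartung adjustment is applied. `i_squared()`
implements the truncated rule `100·max(0, (Q−df)/Q)` and is defined as 0
at Q = 0. Categories contributed to by a single comparison are reported
with `Q`, `p_Q` and `i2` as `NA` rather than dropped, so report shapes
stay stable.

## Publication bias

`egger_test()` is the classic unweighted OLS of `d/se` on `1/se` with a
two-tailed t-test of the intercept on n−2 df — the near-universal
default among the weighted variants. Degenerate designs (all SEs equal,
making precision collinear with the intercept) raise an explicit error.
`begg_test()` is the companion rank test: Kendall τ-b between the
variance-standardized deviates from the fixed-effect mean and the
variances, with a normal-approximation p. Both run on comparison-level
composites, consistent with the pooled unit of analysis.

## Moderator meta-regressions

`meta_regress()` fits one moderator at a time (age, total training
hours, risk-of-bias composite), never jointly and without
multiple-testing correction, mirroring how such analyses are reported in
this literature. Residual τ² uses the method-of-moments generalization
of DL: from the fixed-effect WLS fit,
`τ² = max(0, (Q_E − (n−p)) / tr(P))`, `P = W − WX(X'WX)⁻¹X'W`, then one
refit with weights `1/(vᵢ+τ²)`. The slope is tested with
`Q_model = (β̂/se)²` against χ²(1). Moderators are study-level: every
comparison of a study inherits its value; comparisons with a missing
moderator are dropped and counted (`n_dropped`). A constant moderator or
fewer than three usable comparisons is an error at the single-fit level
and a recorded skip in `run_moderator_suite()`.

## The synthetic generator

`generate_dataset()` emulates exactly the structure the analysis
assumes, on the standardized scale (pretest SD ≈ 1) so true effects map
directly onto d:

* per study and covered category, a true effect
  `θ_sc = δ_c + N(0, τ²)`;
* per arm and measure, sample pre/post means drawn jointly normal with
  correlation `rho_prepost_true` and variance 1/n, and sample SDs from
  their χ² sampling distribution — so the variance formula's ρ
  assumption can be stress-tested by generating at 0.7 and analyzing at
  0.5 (the mismatch inflates assumed variances and pushes τ̂² toward
  zero, which a test verifies directionally);
* a control-type mixture, optional second control arm
  (`multi_arm_prob`), lower-is-better directions at `direction_prob`,
  and study-level moderators (age 4–18 years, dose 1.5–18 hours,
  risk-of-bias domain ratings drawn at low/unclear/high ≈ .36/.47/.17,
  the published per-domain marginals averaged).

Generation is deterministic given the config seed; the caller's RNG
state is saved and restored. `apply_selection()` implements p-dependent
selective publication: studies whose smallest category p exceeds a
threshold are suppressed with a given probability, with a full
suppression log.

`preset_mbi_review()` encodes the study conditions of the published
youth-MBI evidence base: 33 trials, arm sizes 9–100 (totalling roughly
3,500–4,000 participants), category coverage probabilities equal to the
reported per-category study counts over 33, a control-type mix giving
about half the trials an active-type control, true per-category effects
equal to the reported pooled estimates (0.16–0.30), and τ² = 0.05
(consistent with the moderate-to-substantial I² values reported). These
defaults were fixed once from those published marginals and are not
tuning knobs.

What the generator does *not* emulate: raw instrument scales (verifiable
standardized effects were preferred over raw-scale realism), correlated
sampling error between instruments within a study (drawn independent,
while the analysis assumes correlation 1 — so composite variances are
conservative relative to the generator's truth), correlated true effects
across categories within a study, follow-up time points, and
item-level/participant-level data. Passing tests therefore demonstrate
estimator correctness under the stated model, not robustness to every
feature of real extraction data.

## Numerical and testing choices

Worked-example identities are asserted exactly (I² from published Q/df
pairs, the −5…5 risk-of-bias scale). Estimator implementations are
cross-checked against an independent meta-analysis package and against
brute-force oracles (explicit Q summation, closed-form simple
regression, exhaustive Kendall pair counting) at 1e-10. Simulation-based
checks use fixed seeds and sizes chosen so Monte-Carlo error is small
relative to the asserted bounds: CI coverage over 500 replicate
meta-analyses of k = 30; Egger type-I error over 2000 null replicates of
k = 20; DL recovery averaged over 5 replicate k = 200 meta-analyses
(a single replicate has an MC SE of ~0.024, too close to the 0.05
recovery band to be a reliable single-draw check). The end-to-end null
check runs the review-shaped preset with all δ_c = 0 over 20 seeds and
requires each category's *mean* pooled d to stay within ±0.1: with ~8–25
comparisons per category the per-seed pooled SE is ~0.08–0.12, so
individual replicates are expected to exceed 0.1 occasionally even under
a perfect null, while the mean over 20 seeds (SE ≈ 0.02) cleanly
separates "no systematic effect" from bias.

Tie-breaks and degenerate inputs: aggregate composites sort measures by
name so results are invariant to input row order; pooled tables order
categories canonically; `i_squared` truncates at zero; `dl_tau2` errors
on C = 0 (k = 1); Egger's t is defined as 0 for all-zero effects and ±∞
at an exact fit with nonzero intercept.

## Known limitations

Shared-arm dependencies are flagged, not modelled. The two assumed
correlations are exactly that — assumed; results should be reported with
the values used. p-values are asymptotic (z and χ²), optimistic at very
small k. The moderator suite inherits the usual caveats of observational
meta-regression with few studies per category. And absolute
reproduction of any particular published pooled value requires the
per-study effect sizes from that publication's supplementary material as
input; the package reproduces the *identities* recoverable from printed
summary tables and validates everything else by simulation.
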