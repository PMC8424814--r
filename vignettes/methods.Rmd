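---
title: "Methods: counterfactual analysis of clinical pharmacy intervention acceptance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: counterfactual analysis of clinical pharmacy intervention acceptance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, its assumptions, every
tunable parameter, the synthetic data generator, and the numerical and
design decisions behind `cpimpact`. It intentionally states no empirical
result: all quantitative claims about the package's behaviour live in the
test suite (`tests/testthat/`) and the acceptance script
(`scripts/acceptance.R`), which recompute them from scratch.

## 1. Problem setting

A clinical pharmacy intervention (CPI) is a pharmacist's recommendation
to a physician about an inpatient prescription. Each CPI is either
accepted or rejected. The target estimand is the effect of acceptance on
post-index outcomes — primarily **losta**, the length of stay after the
admission's first intervention (days) — framed counterfactually: the
expected change in outcome if all CPIs of an admission had been accepted.

Rejected CPIs are not a random subset, so a naive accepted-vs-rejected
comparison is confounded by patient severity and recommendation
character. The package instead (i) builds a predictive model of the
outcome from rich admission and intervention features, (ii) edits the
treatment features of factual records to their "accepted" counterfactual
values, and (iii) compares paired factual and counterfactual predictions.
This is an outcome-regression (g-computation-style) estimator; its
validity rests on the assumptions in section 7 below.

## 2. Record consolidation

The raw unit is one CPI log row. The modelling unit is the
**consolidated record**: one row per (admission, acceptance status),
so an admission with both accepted and rejected CPIs yields two rows.
Consolidation (`consolidate_dataset()`):

* aggregates the thirteen recommendation-type flags by logical OR;
* carries the admission's demographics, twenty risk flags, stay
  variables and outcomes unchanged;
* takes `phase` from the earliest `cpi_order`;
* computes `total_cpi`, the admission's total intervention count; and
* computes ten ordinal scores on $[0,1]$, each the mean over the CPIs in
  scope of a per-CPI quantity: problem complexity, problem intention,
  clinical domain, prescribing step, consultancy, outcomes-driven,
  rejection (share of rejected CPIs), combined clinical-pharmacist
  success, physician rejection, and diagnosis revision. Provider success
  scores use empirical acceptance rates computed from the *whole* log
  (`compute_provider_rates()`), so a record's score reflects how
  successful its pharmacists and physicians are in general.

`score_scope` chooses whether scores average over the whole admission
(`"admission"`), only the CPIs of the record's own status
(`"subgroup"`), or the package default `"mixed"` (status-specific for
scores that define the status contrast, admission-wide for context
scores). This is an open design decision: `"mixed"` matches the intended
interpretation of each score, but `"subgroup"` is defensible when the
two records of an admission should be maximally distinct.

## 3. Feature schema and encoding

`cpi_feature_schema()` maps consolidated columns to numeric model inputs
(binary indicators for flags and factor levels, identity for continuous
variables). Three subsets exist: `"all"` (54 inputs), `"matched"` (36),
and `"unmatched"` (18) — the default for outcome modelling, optionally
plus the acceptance-status indicator (`include_status = TRUE`, giving
19). The unmatched set excludes variables that are balanced between
statuses by construction, keeping the model focused on inputs that can
carry a status contrast.

Encoding (`encode_features()`) standardises continuous inputs (z-score
by default, min–max optional). The scaling is **frozen** at fit time and
re-applied verbatim to every later query, including counterfactual ones;
zero-spread columns get spread 1 so constants encode to 0 rather than
NaN.

## 4. The kernel exemplar network

The predictor is a Nadaraya–Watson regression with a Gaussian product
kernel (often called a generalized regression neural network, GRNN):

$$\hat f(x) = \frac{\sum_i y_i\,K_\sigma(x,x_i)}{\sum_i K_\sigma(x,x_i)},
\qquad K_\sigma(x,x_i)=\exp\Big(-\tfrac12\sum_k (x_k-x_{ik})^2/\sigma_k^2\Big).$$

For categorical outcomes the per-class kernel mass replaces the weighted
mean; ties break toward the more frequent class, then lexicographically.
Numerical choices:

* Kernel weights are computed with a per-query max-shift
  ($e_{ij} - \max_j e_{ij}$ before exponentiation), so the $\sigma \to 0$
  limit is exactly nearest-exemplar prediction instead of 0/0.
* $\sigma_k = \infty$ removes feature $k$ from the metric with no
  residual contribution, so pruned inputs cannot move predictions at all.

### Bandwidth selection

The criterion is **grouped leave-one-admission-out** error (RMSE for
continuous, error rate for categorical): predicting any record of an
admission excludes *all* records of that admission. The two consolidated
records of one admission share the observed outcome; ordinary
leave-one-out would leak it through the "twin" record and select
near-zero bandwidths.

* **Single bandwidth** (default of `fit_outcome_model()`): a log-spaced
  grid of 32 candidates over $10^{-3}$–$10^{3}$, refined by
  golden-section search.
* **Per-feature (ARD) bandwidths** (`per_feature = TRUE`, the pipeline
  default): starting from the best single bandwidth, cyclic coordinate
  descent multiplies one $\sigma_k$ at a time by $\{1/4, 1/2, 2, 4\}$ or
  sets it to $\infty$, clamped to $[0.05, 10^3]$. A move is kept only if
  it improves the criterion by more than `relevance_tol` (relative,
  default $10^{-3}$) — larger bandwidths win ties, biasing toward
  smoothness. At most 5 sweeps run, followed by a **backward pruning**
  pass that drops (sets to $\infty$) any feature whose removal worsens
  the criterion by at most `relevance_tol`. Pruning gives parsimony and
  a clean "no effect detected" behaviour: if every treatment feature is
  pruned, counterfactual edits change nothing and the paired test
  returns $p = 1$ by convention.

`grnn_stop_conditions()` bounds the search: `max_cycles` (criterion
evaluations, default $10^6$), `max_seconds` (wall clock, default 120),
`min_improvement` (default $10^{-6}$). With small budgets the per-feature
search may stop at the single-bandwidth solution or even the constant
predictor; the `stop_reason` field reports why the search ended.

`grnn_split()` provides a deterministic largest-remainder train /
holdout / probe split when out-of-sample evaluation is wanted;
`grnn_evaluate()` reports RMSE, MAE and $R^2$ (or accuracy).

## 5. Counterfactual reassignment

A `reassignment_policy()` lists the field edits defining the
counterfactual scenario:

* `"default"`: `status = "accepted"`, `rejection = 0` — the minimal,
  conservative edit (only the treatment indicator and the score that is
  definitionally its mirror).
* `"extended"`: additionally moves the provider-success scores to their
  accepted-group levels. This extrapolates further from the data
  support — success scores correlate with many covariates — and can be
  unstable; it is provided for sensitivity analysis, not as the default.
* `"none"`: identity policy, useful as a negative control.

`run_counterfactual()` re-predicts every record under the edited
features and reports three quantities: the overall mean difference, the
mean difference **over policy-edited records only**, and a paired test.
The distinction matters: if the causal effect operates per affected
admission, the overall mean dilutes it by the share of never-edited
(fully accepted) records, while the edited-record mean targets the
per-affected-admission effect.

Paired tests: Wilcoxon signed-rank for continuous outcomes (zeros
dropped; exact distribution up to 25 untied pairs, normal approximation
beyond; all-zero differences give $p = 1$), continuity-corrected McNemar
for binary ones.

## 6. Variable impacts and group comparisons

`variable_impacts()` ranks inputs by grouped permutation importance:
all encoded columns of one schema group are shuffled jointly (rows
permuted as a block, preserving within-group structure), the increase in
prediction error over the unshuffled baseline is recorded, floored at 0,
and normalised to percentages summing to 100. `n_repeats` (default 5)
averages over shuffles; `method = "sweep"` instead sweeps each input
over 11 quantile steps at the median profile and reports the standard
deviation of predictions — a faster, partial-dependence-style
alternative that ignores interactions. `grouped_impact()` sums member
impacts into named groups with an `"other"` remainder.

`compare_groups()` produces the accepted-vs-rejected descriptive table:
Mann–Whitney U (exact for the smaller group $\le 8$ untied) for
continuous variables, chi-squared without continuity correction for
categorical ones; constant variables and zero-marginal tables give `NA`,
and p-values display blank at $\ge 0.10$ following common reporting
practice. These tests assume independent groups; the two records of one
admission are not independent, so calibration checks in the test suite
keep one record per admission.

`paired_mean_change_n()` gives paired-difference sample sizes
($z$ formula, or $t$ by iteration), and `ann_sample_heuristic()` the
rule-of-thumb exemplar count (inputs × 10 × layers).

## 7. Assumptions of the causal reading

1. **No unmeasured confounding**: all common causes of rejection and
   outcome are among the model inputs.
2. **Overlap**: for edited records, the accepted-state feature profile
   lies within the support of the exemplars.
3. **Consistency / well-defined intervention**: "all CPIs accepted" is
   captured by the policy's feature edits.
4. **Correct smoothing**: the kernel regression approximates the
   conditional mean well at both factual and edited profiles.

Violations bias the estimate in the usual directions; the generator
(section 8) exists precisely to check the pipeline where these assumptions hold
by construction.

## 8. The synthetic registry generator

`generate_cpi_data(default_synth_config())` emulates the structure of a
hospital CPI registry: patients (default 542 — chosen as this package's
own study size; all defaults below are likewise the package's choices)
with occasional second admissions; a zero-truncated negative-binomial
CPI count per admission (size 0.9, mean ≈ 2.9, max 38); two study
phases; adult/pediatric Beta-shaped ages; demographics; twenty
correlated risk flags drawn through a Gaussian-copula frailty
(`frailty_rho = 0.25`) so comorbidities co-occur; three pharmacists with
distinct acceptance probabilities (0.57 / 0.95 / 0.86) and caseload
weights, 40 physicians with gamma-distributed rejection propensities;
thirteen recommendation-type flags; ordinal complexity / intention /
domain codes; and outcomes — log-normal stays on a half-day grid
(losta: `meanlog = log(1.2)`, `sdlog = 1`, capped at 30 days, shifted by
risk-flag coefficients and the frailty), cost linear in stay, logistic
readmission and mortality.

**The planted effect.** The counterfactual losta is drawn first; the
factual value adds `delta_reject` (days, default 0.4) per affected unit:
per admission with any rejection (`delta_scope = "admission"`) or per
rejected CPI (`"per_cpi"`). The generator also returns a per-patient
ledger with both potential outcomes, so tests can verify the invariant
`losta_factual - losta_counterfactual = delta × units` exactly.

**What it does not emulate**: seasonal or secular trends, pharmacist
learning, informative missingness, measurement error in stays,
drug-level detail, correlation between recommendation types and specific
risk flags, or confounding of the *planted* effect itself — rejection
propensity depends on the physician and pharmacist, not on severity, so
the generator tests estimation machinery, not deconfounding.

Generator defaults are the study conditions for the validation suite;
they are never adjusted to make checks pass.

## 9. Pipeline

`run_pipeline(pipeline_config(...))` chains the stages — simulate (or
read a provided log), validate, consolidate, fit (per-feature by
default), counterfactual, impacts, group comparison — with per-stage
seeds derived from a single master seed, wraps stage errors with the
stage name, and can write a JSON report.

## 10. Known limitations

* **Attenuation.** Kernel smoothing shrinks predictions toward the
  conditional mean, so the paired prediction difference underestimates
  the planted per-admission effect; the bias shrinks with sample size
  and with bandwidth, but at realistic sizes the recovered effect is
  materially smaller than the planted one. The validation suite
  therefore checks interval coverage over replicates, not point
  equality.
* **Null calibration of effect detection.** Under a zero-effect
  configuration, the per-feature bandwidth search sometimes retains
  treatment features on chance leave-out gains that are statistically
  indistinguishable from the gains of a genuine moderate effect. No
  relevance threshold separates the regimes, so the paired test's
  rejection rate under the null exceeds its nominal level. Treat a
  significant counterfactual contrast as model-dependent evidence, not
  a calibrated hypothesis test; the permutation-importance ranking and
  the replicate-based interval are the more trustworthy summaries.
* **Dilution of the overall mean.** The all-record mean difference mixes
  edited and untouched records; report the edited-record mean when the
  estimand is per affected admission.
* **Extended policy extrapolation.** The `"extended"` policy moves
  provider-success scores outside their joint support with other
  covariates; use only for sensitivity analysis.
* **Compute.** The grouped-LOO criterion is $O(n^2)$ per evaluation and
  the per-feature search multiplies evaluations by the feature count;
  budgets in `grnn_stop_conditions()` cap the cost, at the price of a
  possibly unconverged search.
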