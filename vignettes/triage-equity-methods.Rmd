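---
title: "Methods: postoperative triage equity, value of care, and phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: postoperative triage equity, value of care, and phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical machinery in `postriage`: the
definitions it implements, the conventions it fixes where a definition
leaves freedom, and what its synthetic cohorts can and cannot tell you
about real data.

## Triage misclassification

Each admission carries two model-predicted probabilities: hospital
mortality and prolonged (≥ 48 h) ICU stay. Relative to a reference
population we define:

- **high acuity**: either risk at or above the reference 75th percentile;
- **low acuity**: both risks strictly below the reference median;
- **intermediate** otherwise.

*Undertriage* is a high-acuity admission in a general ward; *overtriage*
is a low-acuity admission in an ICU. Intermediate admissions can never be
a triage error: the definitions leave a deliberate gap between the 50th
and 75th percentiles, and we preserve it.

Conventions fixed here (the definitions do not force them):

- **Quantile convention.** Linear interpolation between closest order
  statistics (R type 7), used identically by `compute_thresholds()` and by
  the brute-force oracle in the test suite. Consistency matters more than
  the particular choice; at analysis sizes (thousands of admissions) the
  conventions differ by less than the spacing of adjacent scores.
- **Boundary ties.** "Top quartile" is inclusive (≥ q75); "below the
  median" is strict (<). A constant risk score therefore makes everyone
  high-acuity, never low-acuity.
- **Reference population.** Thresholds are computed on the full
  post-exclusion table (one harmonized cohort), not per hospital.
  `fixed_thresholds()` lets you supply externally published cutoffs
  instead.
- **Exclusions.** Index-surgery deaths, admissions shorter than 24 hours
  (strictly — exactly 24 h is kept), and repeat surgeries within an
  admission. Reasons are recorded per dropped row.

## Risk-matched controls

Controls "with similar risk profiles" are found by K-nearest neighbors on
the two risk scores, standardized to zero mean and unit variance over
cases and candidate pool jointly. Candidate pools respect the acuity
definitions: overtriage controls are *low-acuity ward* admissions,
undertriage controls are *high-acuity ICU* admissions. The control cohort
is the **deduplicated union** of each case's k nearest neighbors (default
k = 5, selection with replacement across cases). This is why achieved
control:case ratios vary between analyses instead of being a fixed
sampling ratio. Distance ties break by lowest admission id, making runs
exactly repeatable. No caliper is applied unless requested.

Balance is reported as standardized mean differences,
(mean_case − mean_control) / sqrt((var_case + var_control)/2); a zero
pooled SD yields SMD 0 when the means agree and is flagged undefined
otherwise. On default synthetic cohorts, matching with k ≤ 5 keeps |SMD|
on both risk scores well under 0.1.

## Value of care

Observed mortality is the composite of in-hospital death and discharge to
hospice (the two are mutually exclusive by construction). Expected
mortality is the sum of predicted mortality probabilities — the standard
risk-adjusted observed-to-expected (O:E) construction; "expected" is not
defined more finely than this anywhere we could anchor it, so the sum of
predictions is the declared choice.

For an analysis pairing a case cohort with its control cohort, each
admission's value of care is the inverted cohort O:E ratio divided by a
cost denominator and scaled by one constant *C* per analysis such that the
pooled case+control median equals 1. Two denominator variants exist:

- `per_admission` (default): each admission's own total cost. This is
  what a per-admission scatter of values requires, and it is the variant
  the package treats as primary.
- `median_cost`: the cohort median cost, making the value constant within
  a cohort. Provided because the two readings are both defensible; the
  choice is exposed, not hidden.

Properties guaranteed by construction and enforced by tests: the pooled
median is 1 to within 1e-9 on every completed run, and rescaling all costs
by any positive factor leaves every normalized value unchanged (*C*
absorbs the scale). A cohort with zero observed mortalities makes the
inverted ratio undefined; the package then stops and points to the
optional continuity correction (add 0.5 to observed and expected counts),
which is off by default so that silent adjustment never happens.

## Phenotyping

Clustering uses sociodemographics only: age, the two area deprivation
index ranks (state 1–10, national 1–100), sex, race, and payer. The social
vulnerability index is *excluded* from the default feature set — the
motivating methods text lists it among descriptive variables but not among
clustering inputs — and can be added through the `continuous` argument.

- **Winsorization.** The top and bottom 1% of each continuous variable are
  treated as outliers. We use a rank-based rule — the `floor(n·tail)`
  most extreme observations on each side are replaced by the nearest
  retained order statistic — rather than interpolated quantile limits,
  because it makes winsorization exactly idempotent (reapplication is a
  no-op), which interpolated limits cannot guarantee.
- **Encoding.** One-hot indicators for categoricals (not rescaled beyond
  0/1), winsorized-then-standardized continuous features. Plain K-means on
  this encoding is the simplest faithful reading of "K-means on
  sociodemographic data"; Gower or k-prototypes alternatives are out of
  scope.
- **K-means.** Lloyd iteration from `restarts` (default 10) random
  initializations drawn as distinct data rows, keeping the lowest
  within-cluster sum of squares (WCSS); a degenerate start falls back to
  the Hartigan–Wong algorithm for that restart. Because finitely many
  restarts can leave a larger k in a worse local optimum, the WCSS curve
  is monotonized by carrying forward the better smaller-k fit before
  elbow selection. Cluster indices are canonicalized by descending size,
  then by first centroid coordinate, so labels are stable across runs and
  row permutations.
- **Elbow.** Both axes of the WCSS curve over k = 1–9 are min-max
  normalized to [0, 1]; the selected k maximizes perpendicular distance to
  the chord joining the endpoints. An exactly linear curve has no elbow
  and yields k = 1; ties go to the smallest k. This makes "the inflection
  point" a reproducible, testable rule.

## Comparison tables and multiplicity

Table rows are level-vs-rest contrasts for categoricals (counts and
one-decimal percentages) and median [IQR] rows for continuous variables.
Tests: Pearson chi-square without continuity correction, switching to the
exact conditional (Fisher) test when any expected cell is below 5;
two-sided Wilcoxon rank-sum, exact for groups of ≤ 20 without ties.
Benjamini–Hochberg adjustment is applied across all rows of one table (the
table is the family) and can be switched off per table, since published
tables differ on whether their footnotes claim adjustment. A level that is
absent or universal in the pooled table has no contrast and is reported
with a missing p-value rather than a fabricated one. Display convention:
"<0.001" below 0.001, ">0.99" above 0.99, otherwise two significant
digits.

## Power

`required_cases_two_proportions()` uses the classical pooled-variance
(score-test) normal approximation with unequal allocation: null standard
error from the allocation-weighted pooled proportion, alternative standard
error unpooled. This construction was chosen over the unpooled Wald
formula because its Monte-Carlo rejection rate (same statistic, simulated
binomials) tracks the closed form to about one percentage point at the
small event rates typical of mortality outcomes, where the Wald test runs
several points anticonservative. For means, the standard deviation is a
known planning value and the comparison is the corresponding z test;
`mc_power_two_means()` simulates exactly that statistic. The returned n is
the smallest case count whose closed-form (or simulated) power reaches the
target, so attained power can overshoot the target at very small n purely
through discreteness.

For planning inputs of 4.2% vs 1.4% with 2.4 controls per case, α = 0.05
and 80% power, the pooled construction returns 351 cases (the unpooled
Wald formula would give 461). Published sample sizes computed from similar
inputs by unstated methods should not be treated as oracle values: for the
two-means inputs 0.23 vs 1.71 with SD 1.11 (standardized difference ≈
1.33) any standard formula returns a handful of cases per group, orders of
magnitude below a published figure in the hundreds — consistent with that
figure deriving from considerations the printed inputs do not capture.

## The synthetic cohort generator

The generator exists so the full pipeline is exercisable without protected
health data. What it emulates, and how the defaults were chosen:

- **Risk scores** are Beta-distributed conditional on a latent low/high
  acuity class (defaults: mortality Beta(1.2, 60) / Beta(2.5, 35),
  prolonged-ICU Beta(1.5, 20) / Beta(4, 8), P(high) = 0.35). Only
  percentile cutoffs are externally anchored, not score distributions;
  Beta keeps support in [0, 1] with tunable quartile structure, and the
  defaults put composite mortality near 2–4% — the magnitude of published
  postoperative cohorts.
- **Location** is assigned from *model acuity* — computed with the same
  thresholds, tie conventions, and post-exclusion reference the classifier
  uses — perturbed by the configured triage error rates (defaults:
  P(ICU | low) = 0.08, P(ward | high) = 0.33, giving undertriage roughly a
  third of high-acuity admissions, in line with published cohort
  proportions). Because generator and classifier share the acuity rule,
  zero error rates yield exactly zero overtriage and undertriage labels,
  not approximately zero.
- **Outcomes**: one categorical draw per admission with event probability
  `mortality_calibration × risk_mortality` (default calibration 1), split
  between death and hospice. A single draw can never set both flags, and
  at calibration 1 cohort O:E ratios are centred on 1 by construction —
  the basis of the calibration-recovery test at n = 50,000.
- **Costs** are log-normal with additive log-scale effects of hospital
  length of stay and ICU admission (base $11K, sdlog 0.5), putting cohort
  medians in the $13K–$28K range of published tables.
- **Phenotypes**: a three-component sociodemographic mixture (weights
  0.42 / 0.35 / 0.23) — older Medicare/Medicare-HMO-dominated and
  deprived; socioeconomically advantaged with low deprivation ranks;
  younger with higher Black representation and Medicaid/Medicaid HMO
  coverage. Component separation (≥ 2.5 within-component SDs on age and
  ADI, near-disjoint payer signatures) is set once so that the planted
  structure is genuinely well separated — the regime the recovery claims
  are about — mirroring how sharply the published phenotypes differ.
  Phenotype assignments and acuity classes live in a sidecar returned by
  `ground_truth()`, not in the admission table, so the analysis path
  cannot leak them.
- Ethnicity is deliberately absent from the schema (the motivating data
  reported it unreliable); no downstream stage expects it.

What the generator does **not** emulate: raw EHR time series, diagnosis
and procedure codes, per-hospital heterogeneity, miscalibrated risk
models, informative missingness, or cost-outcome confounding beyond the
LOS/ICU effects. Passing recovery tests therefore demonstrates that the
pipeline's machinery is correct under its stated assumptions — not that
three phenotypes, or any particular triage-error rate, would be found in
real admissions.

## Problem sizes and determinism

The test suite and acceptance script run phenotype recovery on 20
replicates of n = 700 (modal elbow k and adjusted Rand index ≥ 0.9
against planted labels in ≥ 95% of replicates), calibration recovery at
n = 50,000, pipeline runs at n ≈ 1,200–6,000, and Monte-Carlo power checks
at 10,000 replicates — sizes chosen to make Monte-Carlo bands tight
relative to the tested tolerances while keeping a full run in seconds.
Every stochastic step is seeded: the generator from its config, K-means
restarts from an explicit seed (offset per k), simulations from function
arguments. Identical configuration and seed reproduce pipeline outputs
byte for byte, including the hashed manifest.

## Known limitations

- Acuity thresholds are recomputed from the analyzed population by
  default; auditing against fixed external thresholds requires
  `fixed_thresholds()` and changes labels near the cutoffs.
- K-means with one-hot categoricals weights a categorical's contribution
  by its number of levels; results can be sensitive to encoding. The
  encoder is pluggable precisely because this choice is not externally
  anchored.
- The value-of-care constant is fitted per analysis; values are therefore
  comparable within an analysis, not across analyses.
- Exact tests switch on the conventional expected-count-below-5 rule;
  near the boundary the chi-square and exact p-values can differ in the
  second digit.
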