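---
title: "Measuring trial cohort representativeness: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring trial cohort representativeness: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortsuit)
```

## The problem

A clinical trial cohort can fail its target treatment population in two
different ways: its demographic composition can diverge from the
population's (poor *coverage*), or its demographic data can simply be
absent or recorded as an explicit unknown (poor *completeness*). These are
distinct failure modes — a perfectly documented cohort can still
systematically exclude demographic groups, and a representative cohort with
heavy missingness cannot support a reliable similarity assessment.
`cohortsuit` quantifies both over seven demographic features and combines
them into a single suitability percentage.

## The model

For each feature $f$ (age group, gender, ethnicity, weight group, religion,
language, marital status) the trial and target category counts are
normalised into probability vectors $p^f_{\mathrm{trial}}$,
$p^f_{\mathrm{target}}$ over their shared category universe (the union of
the categories observed in either table; categories unseen in one cohort
get probability 0). Coverage uses the Jensen–Shannon divergence to the
midpoint $M^f = (p^f_{\mathrm{trial}} + p^f_{\mathrm{target}})/2$:

$$\mathrm{JSD}^f = \tfrac12\,\mathrm{KL}(p^f_{\mathrm{trial}}\,\|\,M^f) +
\tfrac12\,\mathrm{KL}(p^f_{\mathrm{target}}\,\|\,M^f),\qquad
\mathrm{Coverage}^f = (1-\mathrm{JSD}^f)\times 100\%$$

Completeness is the share of records with a valid value:
$\mathrm{Completeness}^f = n^f_{\mathrm{complete}} / n_{\mathrm{total}}
\times 100\%$, where both nulls and explicit unknown designations
("UNKNOWN", "PATIENT DECLINED", "UNABLE TO OBTAIN", matched
case-insensitively after trimming) count as incomplete. Per-feature scores
aggregate through clinically informed weights (age 0.30, gender 0.25,
ethnicity 0.20, weight 0.10, and 0.05 each for religion, language, marital
status), and the suitability score mixes the two overall metrics:

$$\mathrm{Suitability} = 0.60\cdot\mathrm{Coverage}_{\mathrm{overall}} +
0.40\cdot\mathrm{Completeness}_{\mathrm{overall}}$$

Coverage carries the larger weight because demographic misalignment limits
external validity in a way that statistical missing-data handling cannot
repair. All weights are configuration, not constants: `weight_config()`
validates that feature weights are non-negative and sum to 1 and that the
aggregation pair sums to 1.

### Numerical choices

* **Logarithm base.** The divergence uses base-2 logarithms, so
  $\mathrm{JSD} \le 1$ and the coverage mapping stays in $[0, 100]$. The
  base is configurable, but note that many general-purpose distance
  routines return the *square root* of the divergence and/or use natural
  logs; neither matches the definition above, and `jsd()` deliberately
  returns the plain divergence.
* **Epsilon stabilisation.** A constant $\epsilon = 10^{-10}$ is added to
  every probability term — the leading factor and both terms inside the
  logarithm — without renormalising, so zero probabilities never reach the
  log. This can make a divergence total infinitesimally negative; totals
  are clamped at 0. A consequence worth knowing: `jsd(p, p)` is exactly 0,
  and disjoint-support distributions score within about $10^{-8}$ of 1
  rather than exactly 1.
* **Rounding.** Percentages are carried at full precision everywhere and
  rounded to one decimal only at presentation (print methods, report
  labels).

### Binning conventions

Age groups (years): Neonate/Infant [0, 1), Child/Adolescent [1, 18),
Young Adult [18, 40), Middle-aged [40, 65), Older Adult [65, 80), Elderly
[80, ∞). Weight groups (kg): Underweight (0, 50), Normal [50, 70),
Overweight [70, 90), Obese [90, 120), Severely Obese [120, ∞). The
published group ranges overlap at their boundaries ("1–18", "18–40", …);
this package fixes the half-open `[lower, upper)` convention — a boundary
value belongs to the *upper* group (age 18 is Young Adult, 50 kg is
Normal) — because it makes the bins exhaustive, mutually exclusive and
testable. That convention is this package's choice, not something the
published ranges decide.

### Ethnicity consolidation and missing data

Raw EHR ethnicity labels (dozens of variants) consolidate into seven major
groups (White, Black/African American, Hispanic/Latino, Asian, Other,
Multiple, Unknown) using a prefix-keyed mapping
(`default_ethnicity_map()`): "WHITE - RUSSIAN" inherits the group of its
head word. The full label inventory behind the published consolidation is
not available, so the mapping is configurable and **fails loudly** on an
unmapped label unless a fallback group is configured — silent bucketing
would be invisible in the scores. The consolidated "Unknown" group is
treated as incomplete data: it is excluded from coverage distributions and
counted by the completeness metric. More generally, coverage distributions
are built from complete assignments only, so the two metrics measure
orthogonal aspects — which is exactly what the metric-independence
correlation check presumes. A weighted feature with *no* valid data is a
hard error by default; `renormalise = TRUE` opts into rescaling the
remaining feature weights, recording the exclusion in the result, because
silently renormalising changes the score's meaning.

Religion, language and marital status have no fixed vocabulary: categories
are taken as observed (upper-cased, trimmed), since the distributions are
built from observed counts anyway.

## The simulated-cohort study

`run_validation_study()` mirrors a Phase II/III single-centre enrolment
simulation: cohort sizes drawn from a Gaussian (mean 60, SD 13), rounded to
integers and clipped to [20, 100]; each cohort sampled from the pool by
simple random sampling without replacement; 100 cohorts by default. Each
cohort is scored against the fixed target, and the study reports summary
statistics plus the unique-selection rate (distinct patients used over
total selections).

Two reproducibility choices: per-cohort seeds derive deterministically from
the base seed (base + cohort index), and the pool is sorted by
`patient_id` before sampling, so cohort composition depends only on the
seed and the *set* of patients — never on the row ordering of the source
file, a fragility known to make same-seed runs non-comparable.

### What the synthetic generator emulates — and what it does not

`population_spec()` generates an EHR-like demographics table:
independent per-patient draws of categorical features from configurable
probabilities, ages and weights from truncated Gaussian mixtures, and
per-feature missingness injected as absent values and explicit "UNKNOWN"
designations. The defaults emulate an adult intensive-care source with its
characteristic quality pattern: weight about 53% absent (weight-group
completeness near 47%), language about 32% flagged, age about 5% absent,
other features essentially complete. The default target size is 1,315
patients, the scale of a sepsis treatment cohort extracted from such a
source; the default sampling pool is 5,000 patients (the size of the real
non-case pool is undocumented, so the unique-selection rate of a synthetic
study is reported but not comparable to any published value).

The generator draws features independently, so it does *not* reproduce
real-world correlations between demographics (age–marital status,
ethnicity–language), nor missingness that depends on other fields
(missing-not-at-random patterns), nor any clinical covariates. Passing
tests on synthetic data therefore demonstrate the *metric machinery* —
convergence, determinism, monotone response to designed shifts — not that
any particular real population is well-represented.

## Robustness and independence diagnostics

`correlation_check()` reports Pearson and Spearman correlations with
two-sided p-values from the t approximation (standard practice at n = 100;
an exact permutation p-value is available as an opt-in for n ≤ 8) and a
verdict on the conventional thresholds: weak |r| < 0.3, strong |r| > 0.7.
Weak correlation between coverage and completeness across cohorts supports
combining them into one score.

`run_robustness()` re-aggregates fixed per-cohort per-feature scores under
alternative weight configurations — it never resamples, so scenario
differences isolate the weighting choice. Built-in scenarios: clinical
defaults; equal weights (1/7 each); age-dominant (0.50 on age, the
remaining 0.50 redistributed over the other six features *proportionally
to their clinical weights* — the redistribution rule is underdetermined,
and proportional rescaling preserves the features' relative priorities);
and aggregation mixes 70/30, 60/40, 50/50. Ties in best/worst
identification break toward the lowest cohort index and are flagged. All
spreads are sample standard deviations (n − 1).

## Problem sizes and test design

The package's own validation (testthat suite plus the bundled acceptance
script) runs studies of 100 cohorts against pools of 800–4,000 synthetic
patients and targets of 300–1,315 — sizes chosen to keep sampling error
well inside the asserted tolerances while the whole suite completes in
well under a minute. Stochastic assertions run under fixed seeds with
bounds derived from binomial or correlation null-distribution error
(typically 3 standard errors); divergence and correlation routines are
checked against independently coded brute-force oracles at 1e-9 and 1e-12.

One published arithmetic quirk is deliberately preserved: in the reference
worked example the per-feature coverage scores (98, 91, 89, 86, 82.5, 79,
85) aggregate to 90.525% at full precision, while the printed overall
value is 90% and the printed suitability 89.2% is consistent with using 90
exactly. `cohortsuit` reproduces 88.1% (completeness) and 89.24 → 89.2%
(suitability given 90) exactly and documents — rather than reproduces —
the 90.525 → 90 rounding.

## Known limitations

* Feature weights and the 60/40 aggregation are informed design choices,
  not empirically derived; absolute suitability values move with them
  (rankings are considerably more stable, which is what the robustness
  engine is for).
* Coverage treats categories as unordered even for binned numeric
  features; a one-bin age shift and a three-bin shift cost the same.
* The framework does not model clinical covariates, comorbidities or
  outcomes, and does not impute missing demographics.
* Completeness is measured per feature; record-level completeness (all
  seven features valid) is not part of the score.
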