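# cohortsuit

Quantitative assessment of clinical trial cohort representativeness.

Trial findings only generalise if the enrolled cohort resembles the target
treatment population — yet representativeness is usually judged by eyeballing
demographic tables. `cohortsuit` replaces that with two complementary,
computable metrics over seven demographic features (age group, gender,
ethnicity, weight group, religion, language, marital status):

* **Coverage** — demographic similarity between trial and target, per
  feature: `Coverage^f = (1 − JSD^f) × 100%`, where `JSD^f` is the
  Jensen–Shannon divergence between the two category distributions
  (base-2 logs, so it is bounded by 1; ε = 1e-10 added to every probability
  term for numerical stability).
* **Completeness** — data availability, per feature:
  `Completeness^f = n_complete / n_total × 100%`, counting both nulls and
  explicit unknown designations ("UNKNOWN", "PATIENT DECLINED",
  "UNABLE TO OBTAIN") as incomplete.

Per-feature scores aggregate through clinically informed weights
(age 0.30, gender 0.25, ethnicity 0.20, weight 0.10, religion/language/
marital status 0.05 each), and the overall metrics combine into one score:

```
Suitability = 0.60 · Coverage_overall + 0.40 · Completeness_overall
```

The package also ships a synthetic EHR-like population generator with
configurable per-feature category probabilities and missingness, a
simulated-cohort validation study (Gaussian cohort sizes, mean 60, SD 13,
clipped to 20–100; simple random sampling without replacement), Pearson +
Spearman metric-independence diagnostics, a weight-robustness scenario
engine, and radar-plot data export. It is aimed at trial statisticians and
data-quality teams who need reproducible, auditable representativeness
numbers for protocol design or regulatory documentation.

## Worked example

```r
library(cohortsuit)

pool   <- synthetic_population(population_spec(n_patients = 5000, seed = 101))
target <- synthetic_population(population_spec(n_patients = 1315,
                                               id_prefix = "T", seed = 102))
trial  <- sample_cohort(pool, 60, seed = 7)
score_cohort(trial, target, cohort_id = "demo-trial")
#> <cohortsuit result> cohort demo-trial (n = 60)
#>   suitability 96.6%  (coverage 99.5%, completeness 92.2%)
#>     AGE_GROUP      w=0.30  coverage   99.1  completeness   98.3
#>     GENDER         w=0.25  coverage   99.9  completeness  100.0
#>     ETHNICITY      w=0.20  coverage   99.5  completeness  100.0
#>     WEIGHT_GROUP   w=0.10  coverage   99.3  completeness   43.3
#>     RELIGION       w=0.05  coverage   99.3  completeness  100.0
#>     LANGUAGE       w=0.05  coverage   99.8  completeness   68.3
#>     MARITAL_STATUS w=0.05  coverage   99.8  completeness  100.0
```

Reading this: the cohort's category distributions sit very close to the
target's on every feature (coverage ≈ 99%), but patient weight is absent
for most records (completeness 43.3%) and language for a third — a data
limitation inherited from the source population, whose impact is damped by
those features' low clinical weights. The full simulation study and the
weighting sensitivity analysis:

```r
study <- run_validation_study(pool, target,
                              cohort_sampling_config(n_cohorts = 100, seed = 7))
study
#> <cohortsuit study> 100 cohorts (sizes 37-95, mean 61.8)
#>   unique selection rate 57.8% (6181 selections)
#>   suitability  mean 95.8 (sd 0.57), range 94.1-96.9
#>   coverage     mean 98.6 (sd 0.46), range 97.4-99.5
#>   completeness mean 91.7 (sd 1.17), range 87.5-94.5

correlation_check(study$results$coverage, study$results$completeness)
#> <correlation> n = 100: Pearson r = 0.130 (p = 0.198), Spearman rho = 0.109 (p = 0.282)
#>   association: weak

run_robustness(study)[, 1:7]
#> # A tibble: 6 × 7
#>   scenario           mean    sd   min   max best  worst
#> 1 clinical           95.8 0.573  94.1  96.9 C-030 C-057
#> 2 equal_weights      93.7 0.683  91.7  95.1 C-030 C-057
#> 3 age_dominant       96.3 0.707  94.0  97.7 C-024 C-077
#> 4 aggregation_70_30  96.5 0.505  95.0  97.4 C-030 C-057
#> 5 aggregation_60_40  95.8 0.573  94.1  96.9 C-030 C-057
#> 6 aggregation_50_50  95.1 0.656  93.1  96.5 C-024 C-043
```

The weak coverage–completeness correlation justifies combining them into
one composite score; stable best/worst identities across aggregation
scenarios show the ranking is robust to the 60/40 choice.

A shell interface wraps the same functions
(`inst/scripts/cohortsuit score|simulate|robustness|make-population`);
every run writes a manifest with the resolved configuration and seed.

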