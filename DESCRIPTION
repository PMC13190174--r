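Package: cohortsuit
Title: Quantitative Assessment of Clinical Trial Cohort Representativeness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores how well a clinical trial cohort represents a target
    treatment population by combining two complementary data-quality metrics
    over seven demographic features (age group, gender, ethnicity, weight
    group, religion, language, marital status): demographic coverage, measured
    with an epsilon-stabilised Jensen-Shannon divergence between category
    distributions, and dataset completeness, the proportion of valid
    (non-missing, non-unknown) values. Per-feature scores are aggregated with
    clinically informed weights into a single suitability percentage. Includes
    a synthetic electronic-health-record population generator with
    configurable category probabilities and missingness, a simulated-cohort
    validation study (Gaussian cohort sizes, sampling without replacement),
    metric-independence checks, and a weight-robustness scenario engine, plus
    CSV/YAML/JSON interfaces and radar-plot data export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
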