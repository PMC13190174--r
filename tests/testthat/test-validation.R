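test_that("correlations match hand cases and the brute-force oracle", {
  r <- correlation_check(1:5, 2 * (1:5) + 3)
  expect_equal(r$pearson_r, 1)
  expect_equal(r$spearman_rho, 1)
  expect_equal(correlation_check(1:5, -(1:5))$pearson_r, -1)
  # rank formula: 1 - 6 * sum(d^2) / (n (n^2 - 1)) with sum(d^2) = 4
  r2 <- correlation_check(1:5, c(2, 1, 4, 3, 5))
  expect_equal(r2$spearman_rho, 1 - 6 * 4 / (5 * 24))
  expect_error(correlation_check(1:5, rep(3, 5)), "constant")
  expect_error(correlation_check(1:2, 1:2), "at least 3")

  set.seed(13)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    x <- stats::rnorm(n)
    y <- stats::rnorm(n)
    cc <- correlation_check(x, y)
    expect_equal(cc$pearson_r, oracle_pearson(x, y), tolerance = 1e-12)
    expect_equal(cc$spearman_rho, oracle_spearman(x, y), tolerance = 1e-12)
    expect_true(cc$pearson_p >= 0 && cc$pearson_p <= 1)
  }
})

test_that("verdicts follow the |r| thresholds and permutation p is available", {
  expect_equal(correlation_check(1:10, 10:1)$independence_verdict, "strong")
  set.seed(2)
  x <- stats::rnorm(50)
  y <- stats::rnorm(50)
  expect_equal(correlation_check(x, y)$independence_verdict, "weak")
  p <- correlation_check(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5),
                         permutation_p = TRUE)
  expect_true(p$pearson_p > 0 && p$pearson_p <= 1)
  expect_error(correlation_check(1:9, rnorm(9), permutation_p = TRUE),
               "n <= 8")
})

test_that("size shows no association with scores generated independently", {
  set.seed(17)
  sizes <- sample(20:100, 100, replace = TRUE)
  scores <- stats::rnorm(100, 89, 1.1)
  cc <- size_association(sizes, scores)
  expect_lt(abs(cc$pearson_r), 0.3)
  expect_equal(cc$independence_verdict, "weak")
  expect_equal(size_association(sizes, as.numeric(sizes))$pearson_r, 1)
})

test_that("extreme cohorts are identified with index tie-breaking", {
  tab <- tibble::tibble(cohort_id = c("C-001", "C-002", "C-003"),
                        suitability = c(89.1, 91.6, 86.5))
  e <- identify_extremes(tab)
  expect_equal(e$best, "C-002")
  expect_equal(e$worst, "C-003")
  expect_false(e$best_tie || e$worst_tie)
  single <- identify_extremes(tab[1, ])
  expect_equal(single$best, single$worst)
  tie <- identify_extremes(tibble::tibble(
    cohort_id = c("C-001", "C-002"), suitability = c(90, 90)))
  expect_equal(tie$best, "C-001")
  expect_true(tie$best_tie && tie$worst_tie)
  expect_error(identify_extremes(tab[0, ]), "no cohort")
})

test_that("builtin scenarios carry the documented weight structure", {
  sc <- builtin_scenarios()
  expect_setequal(names(sc),
                  c("clinical", "equal_weights", "age_dominant",
                    "aggregation_70_30", "aggregation_60_40",
                    "aggregation_50_50"))
  expect_equal(unname(sc$equal_weights$feature_weights), rep(1 / 7, 7))
  ad <- sc$age_dominant$feature_weights
  expect_equal(unname(ad["AGE_GROUP"]), 0.50)
  expect_equal(sum(ad), 1)
  # remaining 0.50 preserves the clinical relative priorities
  clin <- clinical_feature_weights()
  others <- setdiff(names(clin), "AGE_GROUP")
  expect_equal(unname(ad[others] / sum(ad[others])),
               unname(clin[others] / sum(clin[others])))
  expect_equal(sc$aggregation_70_30$coverage_weight, 0.70)
})

test_that("re-aggregation under clinical weights reproduces direct scoring", {
  pool <- synthetic_population(population_spec(n_patients = 900, seed = 51))
  tgt <- synthetic_population(population_spec(n_patients = 400,
                                              id_prefix = "T", seed = 52))
  st <- run_validation_study(pool, tgt,
                             cohort_sampling_config(n_cohorts = 20, seed = 6))
  rb <- run_robustness(st)
  per_cohort <- attr(rb, "per_cohort")
  expect_equal(unname(per_cohort[, "clinical"]), st$results$suitability,
               tolerance = 1e-12)
  expect_equal(unname(per_cohort[, "aggregation_60_40"]),
               st$results$suitability, tolerance = 1e-12)
  expect_true(all(rb$min <= rb$mean & rb$mean <= rb$max))
  expect_true(all(rb$sd >= 0))
})

test_that("dominance is preserved under every weight scenario", {
  feats <- feature_names()
  set.seed(33)
  base_cov <- stats::runif(7, 70, 90)
  base_comp <- stats::runif(7, 80, 95)
  tab <- tibble::tibble(cohort_id = c("C-001", "C-002"),
                        cohort_size = c(50L, 50L),
                        coverage = NA_real_, completeness = NA_real_,
                        suitability = NA_real_)
  for (i in seq_along(feats)) {
    tab[[paste0("coverage.", feats[i])]] <- c(base_cov[i] + 3, base_cov[i])
    tab[[paste0("completeness.", feats[i])]] <- c(base_comp[i] + 2,
                                                  base_comp[i])
  }
  rb <- run_robustness(tab)
  expect_true(all(rb$best == "C-001"))
  expect_true(all(rb$worst == "C-002"))

  # identical cohorts: every scenario ties, broken toward the lowest index
  tab2 <- tab
  for (f in feats) {
    tab2[[paste0("coverage.", f)]] <- rep(80, 2)
    tab2[[paste0("completeness.", f)]] <- rep(90, 2)
  }
  rb2 <- run_robustness(tab2)
  expect_true(all(rb2$sd == 0))
  expect_true(all(rb2$best == "C-001" & rb2$worst == "C-001"))
  expect_true(all(rb2$best_tie & rb2$worst_tie))
})

test_that("suitability spread narrows as the completeness weight rises", {
  # construct cohorts where completeness varies less than coverage
  set.seed(44)
  n <- 60
  feats <- feature_names()
  tab <- tibble::tibble(cohort_id = sprintf("C-%03d", 1:n),
                        cohort_size = rep(50L, n),
                        coverage = NA_real_, completeness = NA_real_,
                        suitability = NA_real_)
  cov_level <- stats::rnorm(n, 85, 3)
  comp_level <- stats::rnorm(n, 91, 0.8)
  for (f in feats) {
    tab[[paste0("coverage.", f)]] <- cov_level + stats::rnorm(n, 0, 0.5)
    tab[[paste0("completeness.", f)]] <- comp_level + stats::rnorm(n, 0, 0.2)
  }
  rb <- run_robustness(tab)
  sds <- stats::setNames(rb$sd, rb$scenario)
  expect_gt(sds["aggregation_70_30"], sds["aggregation_60_40"])
  expect_gt(sds["aggregation_60_40"], sds["aggregation_50_50"])
})

test_that("scenario files round-trip through YAML", {
  path <- system.file("extdata", "scenarios.yaml", package = "cohortsuit")
  sc <- read_scenarios(path)
  builtin <- builtin_scenarios()
  expect_setequal(names(sc), names(builtin))
  expect_equal(sc$age_dominant$feature_weights,
               builtin$age_dominant$feature_weights, tolerance = 1e-12)
  expect_equal(sc$aggregation_50_50$coverage_weight, 0.5)
})
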