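test_that("KL and JSD reproduce hand-computed values in bits", {
  # 0.5*log2(4/3) + 0.5*log2(4/5) = 0.0465547...
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.375, 0.625)), 0.046554,
               tolerance = 1e-4)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), 1, tolerance = 1e-6)
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0, 0)), "length")

  # 0.5*(0.046554 + 0.051035) by hand with base-2 logs
  expect_equal(jsd(c(0.5, 0.5), c(0.25, 0.75)), 0.048795, tolerance = 1e-4)
  expect_equal(jsd(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), 1, tolerance = 1e-6)
})

test_that("jsd is symmetric, bounded, near-zero on identity, and matches the brute-force oracle", {
  set.seed(7)
  for (k in 2:5) {
    for (rep in 1:20) {
      p <- random_prob(k)
      q <- random_prob(k)
      d_pq <- jsd(p, q)
      expect_equal(d_pq, jsd(q, p), tolerance = 1e-12)
      expect_gte(d_pq, 0)
      expect_lte(d_pq, 1)
      expect_equal(d_pq, oracle_jsd(p, q), tolerance = 1e-9)
      expect_lte(jsd(p, p), 1e-8)
    }
    # sparse support exercises the epsilon stabilisation
    p <- c(1, rep(0, k - 1))
    q <- c(rep(0, k - 1), 1)
    expect_equal(jsd(p, q), oracle_jsd(p, q), tolerance = 1e-9)
    expect_lte(jsd(p, q), 1)
  }
})

test_that("category distributions normalise counts over the shared universe", {
  a <- tibble::tibble(patient_id = as.character(1:4),
                      GENDER = c("M", "M", "M", "F"))
  d <- category_distribution(a, "GENDER", c("F", "M"))
  expect_equal(d$probs, c(0.25, 0.75))
  expect_equal(d$n_complete, 4)
  # zero-count universe categories are retained with probability 0
  b <- tibble::tibble(patient_id = as.character(1:2), GENDER = c("A", "A"))
  expect_equal(category_distribution(b, "GENDER", c("A", "B"))$probs, c(1, 0))
  b$GENDER <- NA_character_
  expect_error(category_distribution(b, "GENDER", c("A", "B")),
               "no valid data.*GENDER")
})

test_that("coverage and completeness map to percentages with the stated limits", {
  expect_equal(feature_coverage(0), 100)
  expect_equal(feature_coverage(1), 0)
  expect_equal(feature_coverage(0.048795), 95.1205)
  expect_error(feature_coverage(1.2), "\\[0, 1\\]")
  expect_equal(feature_completeness(10, 2, 1), 70)
  expect_equal(feature_completeness(10, 0, 0), 100)
  expect_equal(feature_completeness(4, 4, 0), 0)
  expect_error(feature_completeness(0, 0, 0), "empty cohort")
  expect_error(feature_completeness(3, 3, 1), "exceed")
})

test_that("weighted aggregation reproduces the worked example", {
  completeness <- c(AGE_GROUP = 89, ETHNICITY = 95, GENDER = 100,
                    WEIGHT_GROUP = 62, RELIGION = 80, LANGUAGE = 56,
                    MARITAL_STATUS = 88)
  expect_equal(aggregate_features(completeness), 88.1)
  coverage <- c(GENDER = 98, AGE_GROUP = 91, ETHNICITY = 89,
                WEIGHT_GROUP = 86, RELIGION = 82.5, LANGUAGE = 79,
                MARITAL_STATUS = 85)
  # full-precision weighted sum (presentation rounding happens later)
  expect_equal(aggregate_features(coverage), 90.525)
  expect_equal(suitability(90, 88.1), 89.24)
  expect_equal(round(suitability(90, 88.1), 1), 89.2)
  expect_equal(suitability(100, 100), 100)
  expect_equal(suitability(0, 100), 40)
})

test_that("aggregation is convex and strictly monotone in weighted features", {
  set.seed(21)
  feats <- feature_names()
  for (rep in 1:25) {
    scores <- stats::setNames(stats::runif(7, 0, 100), feats)
    w <- clinical_feature_weights()
    agg <- aggregate_features(scores, w)
    expect_gte(agg, min(scores))
    expect_lte(agg, max(scores))
    f <- sample(feats, 1)
    bumped <- scores
    bumped[f] <- min(100, bumped[f] + 5)
    if (bumped[f] > scores[f]) {
      expect_gt(aggregate_features(bumped, w), agg)
    }
  }
  expect_equal(aggregate_features(stats::setNames(rep(100, 7), feats)), 100)
})

test_that("missing weighted features error unless renormalisation is opted in", {
  scores <- c(AGE_GROUP = 90, GENDER = 95)
  expect_error(aggregate_features(scores), "ETHNICITY")
  out <- aggregate_features(scores, renormalise = TRUE)
  expect_equal(as.numeric(out), (0.30 * 90 + 0.25 * 95) / 0.55)
  expect_setequal(attr(out, "excluded"),
                  c("ETHNICITY", "WEIGHT_GROUP", "RELIGION", "LANGUAGE",
                    "MARITAL_STATUS"))
})

test_that("self-comparison scores exactly 100 and differences stay local", {
  target <- make_records(40, age = rep(c(30, 55, 70, 85), 10),
                         gender = rep(c("Male", "Female"), 20),
                         weight = rep(c(60, 95), 20))
  res <- score_cohort(target, target)
  expect_equal(res$suitability, 100)
  expect_equal(res$coverage_overall, 100)
  expect_equal(res$completeness_overall, 100)

  # perturb only gender: every other feature keeps coverage 100
  trial <- target
  trial$gender <- rep(c("Male", "Male", "Male", "Female"), 10)
  res2 <- score_cohort(trial, target)
  pf <- res2$per_feature
  expect_lt(pf$coverage[pf$feature == "GENDER"], 100)
  expect_equal(pf$coverage[pf$feature != "GENDER"], rep(100, 6))
})

test_that("score_cohort composes the divergence pipeline as hand-computed", {
  # trial gender {M, M, F} vs target {M, F}; everything else identical and
  # complete, so only GENDER contributes a coverage deficit
  trial <- make_records(3, gender = c("Male", "Male", "Female"))
  target <- make_records(2, gender = c("Male", "Female"), prefix = "T")
  res <- score_cohort(trial, target)
  d <- oracle_jsd(c(1 / 3, 2 / 3), c(0.5, 0.5))
  expected_gender_cov <- (1 - d) * 100
  pf <- res$per_feature
  expect_equal(pf$coverage[pf$feature == "GENDER"], expected_gender_cov,
               tolerance = 1e-9)
  expect_equal(res$coverage_overall, 0.75 * 100 + 0.25 * expected_gender_cov,
               tolerance = 1e-9)
  expect_equal(res$completeness_overall, 100)
  expect_equal(res$suitability,
               0.6 * res$coverage_overall + 0.4 * 100, tolerance = 1e-12)
})

test_that("weight configs validate their invariants", {
  expect_error(weight_config(feature_weights = c(AGE_GROUP = 1)), "must name")
  bad <- clinical_feature_weights()
  bad["AGE_GROUP"] <- 0.4
  expect_error(weight_config(feature_weights = bad), "sum to 1")
  expect_error(weight_config(coverage_weight = 0.7), "equal 1")
  expect_error(weight_config(epsilon = 0), "positive")
  w <- weight_config(coverage_weight = 0.7, completeness_weight = 0.3)
  expect_equal(suitability(80, 60, w), 0.7 * 80 + 0.3 * 60)
})
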