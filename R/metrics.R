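# Coverage (Jensen-Shannon based), completeness, and the combined
# suitability score.

#' Category distribution of one feature in one cohort
#'
#' Counts the non-missing assignments of a feature over a shared category
#' universe and normalises to probabilities. Categories absent from the
#' cohort but present in the universe receive probability 0, so that trial
#' and target distributions always share support structure.
#'
#' @param assignments Assignment table from [featurize()].
#' @param feature One of [feature_names()].
#' @param category_universe Ordered character vector of category labels
#'   (typically the union of trial and target observed categories).
#' @return A `cohortsuit_distribution`: list with `feature`, `categories`,
#'   `probs` (summing to 1) and `n_complete`.
#' @export
category_distribution <- function(assignments, feature, category_universe) {
  vals <- assignments[[feature]]
  if (is.null(vals)) stop("feature '", feature, "' not in assignments",
                          call. = FALSE)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    stop("no valid data for feature '", feature,
         "': all assignments are missing", call. = FALSE)
  }
  if (anyDuplicated(category_universe)) {
    stop("category universe must be unique", call. = FALSE)
  }
  extra <- setdiff(unique(vals), category_universe)
  if (length(extra) > 0) {
    stop("observed categories outside the universe for '", feature, "': ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(vals, levels = category_universe))
  structure(list(feature = feature,
                 categories = category_universe,
                 probs = as.numeric(counts) / length(vals),
                 n_complete = length(vals)),
            class = "cohortsuit_distribution")
}

#' Epsilon-stabilised Kullback-Leibler divergence
#'
#' Computes `sum((p + eps) * log((p + eps) / (m + eps)))` in the given log
#' base. The stabilising constant is added to every probability term, without
#' renormalisation, so zero probabilities never reach the logarithm; the
#' epsilon-induced tiny negative totals are clamped to 0.
#'
#' @param p,m Probability vectors of equal length (entries >= 0).
#' @param epsilon Stabilising constant (default 1e-10).
#' @param log_base Logarithm base (default 2, giving bits).
#' @return Non-negative scalar divergence.
#' @examples
#' kl_divergence(c(0.5, 0.5), c(0.375, 0.625)) # 0.046554 bits
#' @export
kl_divergence <- function(p, m, epsilon = 1e-10, log_base = 2) {
  if (length(p) != length(m)) {
    stop("p and m must have the same length", call. = FALSE)
  }
  if (any(p < 0) || any(m < 0)) {
    stop("probabilities must be non-negative", call. = FALSE)
  }
  pe <- p + epsilon
  me <- m + epsilon
  max(0, sum(pe * (log(pe / me) / log(log_base))))
}

#' Jensen-Shannon divergence between two category distributions
#'
#' The average of the two Kullback-Leibler divergences to the midpoint
#' distribution `M = (p + q) / 2`. Symmetric, zero for identical
#' distributions, and bounded by 1 under base-2 logarithms (the base used
#' throughout, so that the coverage mapping stays in \[0, 100\]). The
#' divergence itself is returned — not its square root (the metric form some
#' general-purpose distance routines return), and not the natural-log variant.
#'
#' @param p_trial,p_target Either plain probability vectors of equal length
#'   or `cohortsuit_distribution` objects over the same ordered universe.
#' @param epsilon,log_base As in [kl_divergence()].
#' @return Scalar in \[0, 1\] (for log_base 2).
#' @examples
#' jsd(c(0.5, 0.5), c(0.25, 0.75)) # 0.048795
#' @export
jsd <- function(p_trial, p_target, epsilon = 1e-10, log_base = 2) {
  p <- .dist_probs(p_trial)
  q <- .dist_probs(p_target)
  if (length(p) != length(q)) {
    stop("distributions must share one category universe", call. = FALSE)
  }
  if (inherits(p_trial, "cohortsuit_distribution") &&
      inherits(p_target, "cohortsuit_distribution") &&
      !identical(p_trial$categories, p_target$categories)) {
    stop("distributions must share one ordered category universe",
         call. = FALSE)
  }
  m <- (p + q) / 2
  0.5 * kl_divergence(p, m, epsilon, log_base) +
    0.5 * kl_divergence(q, m, epsilon, log_base)
}

.dist_probs <- function(x) {
  if (inherits(x, "cohortsuit_distribution")) x$probs else as.numeric(x)
}

#' Coverage percentage from a Jensen-Shannon divergence
#'
#' `Coverage = (1 - JSD) * 100`; 100 for identical distributions, 0 for
#' disjoint support.
#'
#' @param jsd_value Scalar (or vector) in \[0, 1\].
#' @return Percentage in \[0, 100\].
#' @export
feature_coverage <- function(jsd_value) {
  if (any(jsd_value < 0 | jsd_value > 1)) {
    stop("jsd_value must lie in [0, 1]", call. = FALSE)
  }
  (1 - jsd_value) * 100
}

#' Completeness percentage of one feature
#'
#' `Completeness = (n_total - n_missing - n_unknown) / n_total * 100`: the
#' proportion of records carrying a valid value, where both nulls and
#' explicit unknown designations count as incomplete.
#'
#' @param n_total Total record count (> 0).
#' @param n_missing Count of null/absent values.
#' @param n_unknown Count of explicit unknown designations.
#' @return Percentage in \[0, 100\].
#' @examples
#' feature_completeness(10, 2, 1) # 70
#' @export
feature_completeness <- function(n_total, n_missing, n_unknown = 0) {
  if (n_total <= 0) stop("empty cohort: n_total must be positive",
                         call. = FALSE)
  if (n_missing + n_unknown > n_total) {
    stop("missing + unknown counts exceed the total", call. = FALSE)
  }
  (n_total - n_missing - n_unknown) / n_total * 100
}

#' Aggregate per-feature scores with feature weights
#'
#' Weighted sum of per-feature percentages (used identically for coverage
#' and completeness). By default a weighted feature with no score is an
#' error; with `renormalise = TRUE` the remaining weights are rescaled to
#' sum to 1 and the exclusion is recorded in an attribute.
#'
#' @param per_feature_scores Named numeric vector of percentages (names from
#'   [feature_names()]).
#' @param feature_weights Named weights summing to 1; default clinical.
#' @param renormalise Allow scoring with features absent from
#'   `per_feature_scores` by rescaling the remaining weights.
#' @return Scalar percentage; if features were excluded, they are listed in
#'   the `"excluded"` attribute.
#' @examples
#' aggregate_features(c(AGE_GROUP = 89, ETHNICITY = 95, GENDER = 100,
#'   WEIGHT_GROUP = 62, RELIGION = 80, LANGUAGE = 56, MARITAL_STATUS = 88))
#' @export
aggregate_features <- function(per_feature_scores,
                               feature_weights = clinical_feature_weights(),
                               renormalise = FALSE) {
  w <- feature_weights[feature_weights > 0]
  have <- names(w) %in% names(per_feature_scores)
  if (!all(have)) {
    missing_feats <- names(w)[!have]
    if (!renormalise) {
      stop("no score for weighted feature(s): ",
           paste(missing_feats, collapse = ", "),
           " (set renormalise = TRUE to rescale the remaining weights)",
           call. = FALSE)
    }
    w <- w[have]
    w <- w / sum(w)
    out <- sum(w * per_feature_scores[names(w)])
    attr(out, "excluded") <- missing_feats
    return(out)
  }
  sum(w * per_feature_scores[names(w)])
}

#' Combined suitability score
#'
#' Convex combination of overall coverage and overall completeness,
#' `Suitability = 0.60 * Coverage + 0.40 * Completeness` under the default
#' aggregation weights.
#'
#' @param coverage_overall,completeness_overall Percentages in \[0, 100\].
#' @param weights A [weight_config()].
#' @return Scalar percentage.
#' @examples
#' suitability(90, 88.1) # 89.24
#' @export
suitability <- function(coverage_overall, completeness_overall,
                        weights = weight_config()) {
  stopifnot(inherits(weights, "cohortsuit_weights"))
  if (any(c(coverage_overall, completeness_overall) < 0) ||
      any(c(coverage_overall, completeness_overall) > 100)) {
    stop("overall scores must lie in [0, 100]", call. = FALSE)
  }
  weights$coverage_weight * coverage_overall +
    weights$completeness_weight * completeness_overall
}

#' Per-feature completeness profile of an assignment table
#'
#' @param assignments Assignment table from [featurize()].
#' @return Named numeric vector of completeness percentages per feature.
#' @export
completeness_profile <- function(assignments) {
  feats <- feature_names()
  n <- nrow(assignments)
  vapply(feats, function(f) {
    flagged <- sum(is.na(assignments[[f]]))
    feature_completeness(n, flagged, 0)
  }, numeric(1))
}

#' Score a trial cohort against a target population
#'
#' Runs the full pipeline: featurization, per-feature category
#' distributions over the shared (union) category universe, Jensen-Shannon
#' coverage, per-feature completeness, weighted aggregation and the combined
#' suitability score. Coverage distributions are built from complete
#' (non-missing) assignments only; incompleteness is measured exclusively by
#' the completeness metric, keeping the two aspects orthogonal.
#'
#' @param trial,target Patient record tables (see [featurize()]), or
#'   pre-featurized assignment tables (detected by their feature columns).
#' @param schema,policy,weights Schema, missing policy and weight config.
#' @param cohort_id Optional identifier carried into the result.
#' @param renormalise Passed to [aggregate_features()]: score even when a
#'   weighted feature has no valid data, rescaling remaining weights.
#' @return A `cohortsuit_result`: list with `cohort_id`, `cohort_size`,
#'   `per_feature` (tibble: feature, weight, coverage, completeness),
#'   `coverage_overall`, `completeness_overall`, `suitability`.
#' @examples
#' tgt <- synthetic_population(population_spec(n_patients = 300, seed = 1))
#' trl <- sample_cohort(tgt, 50, seed = 2)
#' score_cohort(trl, tgt)
#' @export
score_cohort <- function(trial, target, schema = demographic_schema(),
                         policy = missing_policy(),
                         weights = weight_config(),
                         cohort_id = "trial", renormalise = FALSE) {
  trial_a <- .as_assignments(trial, schema, policy)
  target_a <- .as_assignments(target, schema, policy)
  score_assignments(trial_a, target_a, weights = weights,
                    cohort_id = cohort_id, renormalise = renormalise)
}

.as_assignments <- function(x, schema, policy) {
  x <- tibble::as_tibble(x)
  if (all(feature_names() %in% names(x))) return(x)
  featurize(x, schema, policy)
}

#' Score pre-featurized assignment tables
#'
#' Lower-level engine behind [score_cohort()]; useful when the target is
#' featurized once and compared against many cohorts.
#'
#' @inheritParams score_cohort
#' @param trial_assignments,target_assignments Tables from [featurize()].
#' @return A `cohortsuit_result` (see [score_cohort()]).
#' @export
score_assignments <- function(trial_assignments, target_assignments,
                              weights = weight_config(),
                              cohort_id = "trial", renormalise = FALSE) {
  feats <- feature_names()
  cov <- comp <- stats::setNames(rep(NA_real_, length(feats)), feats)
  n_trial <- nrow(trial_assignments)
  for (f in feats) {
    flagged <- sum(is.na(trial_assignments[[f]]))
    comp[[f]] <- feature_completeness(n_trial, flagged, 0)
    universe <- sort(unique(c(trial_assignments[[f]], target_assignments[[f]])))
    universe <- universe[!is.na(universe)]
    has_trial <- flagged < n_trial
    has_target <- any(!is.na(target_assignments[[f]]))
    if (has_trial && has_target) {
      pt <- category_distribution(trial_assignments, f, universe)
      pg <- category_distribution(target_assignments, f, universe)
      cov[[f]] <- feature_coverage(
        min(1, jsd(pt, pg, weights$epsilon, weights$log_base)))
    } else if (!renormalise) {
      stop("no valid data for feature '", f, "' in the ",
           if (has_target) "trial cohort" else "target population",
           call. = FALSE)
    }
  }
  cov_scored <- cov[!is.na(cov)]
  cov_overall <- aggregate_features(cov_scored, weights$feature_weights,
                                    renormalise = renormalise)
  comp_overall <- aggregate_features(comp, weights$feature_weights,
                                     renormalise = renormalise)
  res <- list(
    cohort_id = cohort_id,
    cohort_size = n_trial,
    per_feature = tibble::tibble(
      feature = feats,
      weight = unname(weights$feature_weights[feats]),
      coverage = unname(cov),
      completeness = unname(comp)
    ),
    coverage_overall = as.numeric(cov_overall),
    completeness_overall = as.numeric(comp_overall),
    suitability = suitability(as.numeric(cov_overall),
                              as.numeric(comp_overall), weights),
    excluded_features = attr(cov_overall, "excluded")
  )
  class(res) <- "cohortsuit_result"
  res
}

#' @export
print.cohortsuit_result <- function(x, ...) {
  cat(sprintf("<cohortsuit result> cohort %s (n = %d)\n",
              x$cohort_id, x$cohort_size))
  cat(sprintf("  suitability %.1f%%  (coverage %.1f%%, completeness %.1f%%)\n",
              x$suitability, x$coverage_overall, x$completeness_overall))
  pf <- x$per_feature
  for (i in seq_len(nrow(pf))) {
    cat(sprintf("    %-14s w=%.2f  coverage %6s  completeness %6.1f\n",
                pf$feature[i], pf$weight[i],
                ifelse(is.na(pf$coverage[i]), "--",
                       sprintf("%.1f", pf$coverage[i])),
                pf$completeness[i]))
  }
  invisible(x)
}

#' Flatten a scoring result to a one-row tibble
#'
#' @param x A `cohortsuit_result`.
#' @param per_feature Include per-feature coverage/completeness columns.
#' @return One-row tibble.
#' @export
as_tibble_result <- function(x, per_feature = TRUE) {
  stopifnot(inherits(x, "cohortsuit_result"))
  row <- tibble::tibble(
    cohort_id = x$cohort_id, cohort_size = x$cohort_size,
    coverage = x$coverage_overall, completeness = x$completeness_overall,
    suitability = x$suitability
  )
  if (per_feature) {
    for (i in seq_len(nrow(x$per_feature))) {
      f <- x$per_feature$feature[i]
      row[[paste0("coverage.", f)]] <- x$per_feature$coverage[i]
      row[[paste0("completeness.", f)]] <- x$per_feature$completeness[i]
    }
  }
  row
}
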