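# Metric-independence checks, extreme-cohort identification, and the
# weight-robustness scenario engine.

#' Correlation between two cohort-level metrics
#'
#' Computes Pearson's product-moment correlation (linear association) and
#' Spearman's rank correlation (monotonic association) with two-sided
#' p-values from the t approximation, and classifies the strength of
#' association on the conventional thresholds: weak (|r| < 0.3), strong
#' (|r| > 0.7), moderate otherwise. A weak verdict supports treating the two
#' metrics as capturing distinct aspects, justifying their combination into
#' a composite score.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @param permutation_p Opt-in exact permutation p-values (all n!
#'   pairings), available for n <= 8.
#' @return Object of class `cohortsuit_correlation` with `pearson_r`,
#'   `pearson_p`, `spearman_rho`, `spearman_p`, `n`,
#'   `independence_verdict`.
#' @examples
#' correlation_check(1:5, c(2, 1, 4, 3, 5))
#' @export
correlation_check <- function(x, y, permutation_p = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  pear <- stats::cor.test(x, y, method = "pearson")
  spear <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  pearson_p <- unname(pear$p.value)
  spearman_p <- unname(spear$p.value)
  if (permutation_p) {
    if (n > 8) stop("exact permutation p-values limited to n <= 8",
                    call. = FALSE)
    perms <- .permutations(n)
    r_obs <- abs(stats::cor(x, y))
    rho_obs <- abs(stats::cor(x, y, method = "spearman"))
    r_perm <- apply(perms, 1, function(p) abs(stats::cor(x, y[p])))
    rho_perm <- apply(perms, 1, function(p)
      abs(stats::cor(x, y[p], method = "spearman")))
    pearson_p <- mean(r_perm >= r_obs - 1e-12)
    spearman_p <- mean(rho_perm >= rho_obs - 1e-12)
  }
  r <- unname(pear$estimate)
  verdict <- if (abs(r) < 0.3) "weak" else if (abs(r) > 0.7) "strong" else
    "moderate"
  structure(list(pearson_r = r, pearson_p = pearson_p,
                 spearman_rho = unname(spear$estimate),
                 spearman_p = spearman_p, n = n,
                 independence_verdict = verdict),
            class = "cohortsuit_correlation")
}

# all permutations of 1:n as a matrix (n! rows); fine for n <= 8
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1)
  }
  out
}

#' @export
print.cohortsuit_correlation <- function(x, ...) {
  cat(sprintf("<correlation> n = %d: Pearson r = %.3f (p = %.3g), Spearman rho = %.3f (p = %.3g)\n",
              x$n, x$pearson_r, x$pearson_p, x$spearman_rho, x$spearman_p))
  cat("  association:", x$independence_verdict, "\n")
  invisible(x)
}

#' Association between cohort size and a score
#'
#' Same contract as [correlation_check()] applied to (size, score) pairs;
#' a weak verdict indicates representativeness is attainable regardless of
#' enrolment size within the tested range.
#'
#' @param sizes Integer cohort sizes.
#' @param scores Numeric scores (same length).
#' @param ... Passed to [correlation_check()].
#' @return A `cohortsuit_correlation`.
#' @export
size_association <- function(sizes, scores, ...) {
  correlation_check(as.numeric(sizes), scores, ...)
}

#' Identify the best- and worst-performing cohorts
#'
#' Argmax and argmin of suitability. Ties are broken toward the lowest
#' cohort index and flagged.
#'
#' @param results Study results tibble (needs `cohort_id` and
#'   `suitability`), or a `cohortsuit_study`.
#' @return List with `best`, `worst` (cohort ids), `best_index`,
#'   `worst_index`, `best_tie`, `worst_tie`.
#' @export
identify_extremes <- function(results) {
  if (inherits(results, "cohortsuit_study")) results <- results$results
  results <- tibble::as_tibble(results)
  if (nrow(results) == 0) stop("no cohort results", call. = FALSE)
  s <- results$suitability
  bi <- which.max(s); wi <- which.min(s)
  list(best = results$cohort_id[bi], worst = results$cohort_id[wi],
       best_index = bi, worst_index = wi,
       best_tie = sum(s == s[bi]) > 1, worst_tie = sum(s == s[wi]) > 1)
}

#' Built-in robustness scenarios
#'
#' The weighting perturbations examined by the robustness analysis:
#' `clinical` (the default weights), `equal_weights` (1/7 per feature),
#' `age_dominant` (0.50 on age, the remaining 0.50 redistributed over the
#' other six features proportionally to their clinical weights), and three
#' aggregation mixes `aggregation_70_30`, `aggregation_60_40`,
#' `aggregation_50_50` (coverage/completeness) at clinical feature weights.
#'
#' @return Named list of [weight_config()] objects.
#' @export
builtin_scenarios <- function() {
  clin <- clinical_feature_weights()
  others <- clin[setdiff(names(clin), "AGE_GROUP")]
  age_dom <- c(AGE_GROUP = 0.50, others * (0.50 / sum(others)))
  list(
    clinical = weight_config(),
    equal_weights = weight_config(
      feature_weights = stats::setNames(rep(1 / 7, 7), feature_names())),
    age_dominant = weight_config(feature_weights = age_dom),
    aggregation_70_30 = weight_config(coverage_weight = 0.70,
                                      completeness_weight = 0.30),
    aggregation_60_40 = weight_config(coverage_weight = 0.60,
                                      completeness_weight = 0.40),
    aggregation_50_50 = weight_config(coverage_weight = 0.50,
                                      completeness_weight = 0.50)
  )
}

#' Read robustness scenarios from YAML
#'
#' The file holds a map of scenario name to a weight-config block (same keys
#' as [read_weight_config()]).
#'
#' @param path Path to a YAML file.
#' @return Named list of [weight_config()] objects.
#' @export
read_scenarios <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(sc) {
    fw <- if (is.null(sc$feature_weights)) clinical_feature_weights() else
      unlist(sc$feature_weights)
    weight_config(feature_weights = fw,
                  coverage_weight = sc$coverage_weight %||% 0.60,
                  completeness_weight = sc$completeness_weight %||% 0.40,
                  epsilon = sc$epsilon %||% 1e-10,
                  log_base = sc$log_base %||% 2)
  })
}

#' Re-score cohorts under alternative weighting scenarios
#'
#' Re-aggregates fixed per-cohort per-feature coverage and completeness
#' scores under each scenario's weights — no resampling and no recomputation
#' of the underlying divergences, so scenario differences isolate the effect
#' of the weighting choices.
#'
#' @param feature_scores Study results tibble carrying `cohort_id` and the
#'   per-feature `coverage.<FEATURE>` / `completeness.<FEATURE>` columns
#'   (as produced by [run_validation_study()]), or a `cohortsuit_study`.
#' @param scenarios Named list of [weight_config()]s; default
#'   [builtin_scenarios()].
#' @return Tibble with one row per scenario: `scenario`, `mean`, `sd`
#'   (sample SD), `min`, `max`, `best`, `worst`, `best_tie`, `worst_tie`.
#'   The per-cohort suitability matrix is attached as attribute
#'   `"per_cohort"`.
#' @export
run_robustness <- function(feature_scores, scenarios = builtin_scenarios()) {
  if (inherits(feature_scores, "cohortsuit_study")) {
    feature_scores <- feature_scores$results
  }
  feature_scores <- tibble::as_tibble(feature_scores)
  if (is.null(names(scenarios)) || any(!nzchar(names(scenarios)))) {
    stop("scenarios must be a named list", call. = FALSE)
  }
  feats <- feature_names()
  cov_cols <- paste0("coverage.", feats)
  comp_cols <- paste0("completeness.", feats)
  missing_cols <- setdiff(c(cov_cols, comp_cols), names(feature_scores))
  if (length(missing_cols) > 0) {
    stop("feature_scores lacks per-feature columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cov_m <- as.matrix(feature_scores[cov_cols])
  comp_m <- as.matrix(feature_scores[comp_cols])
  colnames(cov_m) <- colnames(comp_m) <- feats

  rows <- vector("list", length(scenarios))
  per_cohort <- matrix(NA_real_, nrow(feature_scores), length(scenarios),
                       dimnames = list(feature_scores$cohort_id,
                                       names(scenarios)))
  for (k in seq_along(scenarios)) {
    w <- scenarios[[k]]
    stopifnot(inherits(w, "cohortsuit_weights"))
    fw <- w$feature_weights[feats]
    suit <- w$coverage_weight * as.numeric(cov_m %*% fw) +
      w$completeness_weight * as.numeric(comp_m %*% fw)
    per_cohort[, k] <- suit
    ext <- identify_extremes(tibble::tibble(
      cohort_id = feature_scores$cohort_id, suitability = suit))
    rows[[k]] <- tibble::tibble(
      scenario = names(scenarios)[k],
      mean = mean(suit),
      sd = if (length(suit) > 1) stats::sd(suit) else 0,
      min = min(suit), max = max(suit),
      best = ext$best, worst = ext$worst,
      best_tie = ext$best_tie, worst_tie = ext$worst_tie
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "per_cohort") <- per_cohort
  out
}
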