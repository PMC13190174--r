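# Weight configuration: per-feature aggregation weights plus the
# coverage/completeness mixing weights of the suitability score.

#' Clinical default feature weights
#'
#' The clinically informed weights prioritise age, gender and ethnicity as
#' the primary determinants of pharmacological response and generalisability:
#' AGE_GROUP 0.30, GENDER 0.25, ETHNICITY 0.20, WEIGHT_GROUP 0.10 and 0.05
#' each for RELIGION, LANGUAGE and MARITAL_STATUS.
#'
#' @return Named numeric vector over [feature_names()], summing to 1.
#' @export
clinical_feature_weights <- function() {
  c(AGE_GROUP = 0.30, GENDER = 0.25, ETHNICITY = 0.20, WEIGHT_GROUP = 0.10,
    RELIGION = 0.05, LANGUAGE = 0.05, MARITAL_STATUS = 0.05)
}

#' Weight configuration
#'
#' @param feature_weights Named non-negative weights over the seven features,
#'   summing to 1 (within 1e-9). Default: [clinical_feature_weights()].
#' @param coverage_weight,completeness_weight Mixing weights of the
#'   suitability score; must sum to 1. Defaults 0.60 / 0.40: coverage is
#'   weighted higher because demographic misalignment limits external
#'   validity in a way missing data cannot be statistically repaired.
#' @param epsilon Stabilising constant added to every probability term before
#'   logarithms in the divergence computation (default 1e-10).
#' @param log_base Logarithm base for the divergences. The default 2 bounds
#'   the Jensen-Shannon divergence by 1, so coverage stays in \[0, 100\].
#' @return Object of class `cohortsuit_weights`.
#' @examples
#' weight_config()
#' weight_config(coverage_weight = 0.7, completeness_weight = 0.3)
#' @export
weight_config <- function(feature_weights = clinical_feature_weights(),
                          coverage_weight = 0.60,
                          completeness_weight = 0.40,
                          epsilon = 1e-10, log_base = 2) {
  feats <- feature_names()
  if (!all(feats %in% names(feature_weights))) {
    stop("feature_weights must name all of: ",
         paste(feats, collapse = ", "), call. = FALSE)
  }
  feature_weights <- feature_weights[feats]
  if (any(feature_weights < 0)) {
    stop("feature weights must be non-negative", call. = FALSE)
  }
  if (abs(sum(feature_weights) - 1) > 1e-9) {
    stop("feature weights must sum to 1 (got ",
         format(sum(feature_weights)), ")", call. = FALSE)
  }
  if (abs(coverage_weight + completeness_weight - 1) > 1e-9) {
    stop("coverage_weight + completeness_weight must equal 1", call. = FALSE)
  }
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  if (log_base <= 1) stop("log_base must exceed 1", call. = FALSE)
  structure(list(feature_weights = feature_weights,
                 coverage_weight = coverage_weight,
                 completeness_weight = completeness_weight,
                 epsilon = epsilon, log_base = log_base),
            class = "cohortsuit_weights")
}

#' @export
print.cohortsuit_weights <- function(x, ...) {
  cat("<cohortsuit weights>\n")
  cat("  features:",
      paste(sprintf("%s=%.4g", names(x$feature_weights), x$feature_weights),
            collapse = ", "), "\n")
  cat(sprintf("  aggregation: coverage %.2f / completeness %.2f, epsilon %g, log base %g\n",
              x$coverage_weight, x$completeness_weight, x$epsilon, x$log_base))
  invisible(x)
}

#' Read a weight configuration from YAML or JSON
#'
#' Expected keys: `feature_weights` (map feature -> weight),
#' `coverage_weight`, `completeness_weight`, optional `epsilon`, `log_base`.
#' Absent keys fall back to the clinical defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [weight_config()].
#' @export
read_weight_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  fw <- clinical_feature_weights()
  if (!is.null(cfg$feature_weights)) {
    fw <- unlist(cfg$feature_weights)
  }
  weight_config(
    feature_weights = fw,
    coverage_weight = cfg$coverage_weight %||% 0.60,
    completeness_weight = cfg$completeness_weight %||% 0.40,
    epsilon = cfg$epsilon %||% 1e-10,
    log_base = cfg$log_base %||% 2
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
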