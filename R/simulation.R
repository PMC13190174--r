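# Synthetic EHR-like population generator and the simulated-cohort
# validation study: Gaussian cohort sizes, simple random sampling without
# replacement, per-cohort scoring against a fixed target.

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
# NULL seed means: use the current RNG stream as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

.categorical_feature <- function(probs, missing_rate = 0, unknown_rate = 0) {
  probs <- unlist(probs)
  if (abs(sum(probs) - 1) > 1e-9) {
    stop("category probabilities must sum to 1", call. = FALSE)
  }
  if (any(probs < 0)) stop("category probabilities must be non-negative",
                           call. = FALSE)
  if (missing_rate < 0 || unknown_rate < 0 ||
      missing_rate + unknown_rate > 1) {
    stop("missing_rate + unknown_rate must lie in [0, 1]", call. = FALSE)
  }
  list(probs = probs, missing_rate = missing_rate, unknown_rate = unknown_rate)
}

.numeric_feature <- function(means, sds, mix = 1, min, max, missing_rate = 0) {
  if (length(means) != length(sds) || length(means) != length(mix)) {
    stop("means, sds and mix must have equal length", call. = FALSE)
  }
  if (abs(sum(mix) - 1) > 1e-9) stop("mixture weights must sum to 1",
                                     call. = FALSE)
  if (missing_rate < 0 || missing_rate > 1) {
    stop("missing_rate must lie in [0, 1]", call. = FALSE)
  }
  list(means = means, sds = sds, mix = mix, min = min, max = max,
       missing_rate = missing_rate)
}

#' Synthetic population specification
#'
#' Describes an EHR-like demographics table: per-feature category
#' probabilities with per-feature missingness and explicit unknown rates for
#' the categorical features, and truncated Gaussian mixtures for age and
#' weight. The defaults emulate an adult intensive-care population with the
#' characteristic quality pattern of such sources — heavily incomplete
#' patient weight (about 53% absent), language about 32% flagged (partly
#' explicit "UNKNOWN" designations), mild age incompleteness, and
#' essentially complete gender, ethnicity, religion and marital status.
#'
#' @param n_patients Number of patients to generate.
#' @param gender,ethnicity,religion,language,marital_status Each a list with
#'   `probs` (named category probabilities summing to 1) and optional
#'   `missing_rate`, `unknown_rate` in \[0, 1\] with sum at most 1.
#' @param age,weight Each a list with mixture `means`, `sds`, `mix` weights,
#'   truncation `min`/`max`, and optional `missing_rate`.
#' @param seed Default random seed used by [synthetic_population()].
#' @param id_prefix Prefix for generated patient identifiers.
#' @return Object of class `cohortsuit_population_spec`.
#' @export
population_spec <- function(
    n_patients = 5000,
    gender = list(probs = c(MALE = 0.56, FEMALE = 0.44)),
    ethnicity = list(probs = c(
      "WHITE" = 0.70, "BLACK/AFRICAN AMERICAN" = 0.10,
      "HISPANIC/LATINO" = 0.05, "ASIAN" = 0.03,
      "OTHER" = 0.10, "MULTI RACE ETHNICITY" = 0.02)),
    religion = list(probs = c(
      "CATHOLIC" = 0.40, "PROTESTANT QUAKER" = 0.15, "JEWISH" = 0.10,
      "NOT RELIGIOUS" = 0.15, "OTHER" = 0.20)),
    language = list(probs = c(
      "ENGL" = 0.85, "SPAN" = 0.05, "RUSS" = 0.03, "PORT" = 0.02,
      "CANT" = 0.02, "OTHER" = 0.03),
      missing_rate = 0.222, unknown_rate = 0.100),
    marital_status = list(probs = c(
      "MARRIED" = 0.45, "SINGLE" = 0.30, "WIDOWED" = 0.12,
      "DIVORCED" = 0.08, "SEPARATED" = 0.03, "LIFE PARTNER" = 0.02)),
    age = list(means = 65, sds = 17, mix = 1, min = 18, max = 95,
               missing_rate = 0.048),
    weight = list(means = 81, sds = 23, mix = 1, min = 35, max = 200,
                  missing_rate = 0.527),
    seed = NULL, id_prefix = "P") {
  if (n_patients < 1) stop("n_patients must be at least 1", call. = FALSE)
  spec <- list(
    n_patients = as.integer(n_patients),
    categorical = list(
      gender = do.call(.categorical_feature, gender),
      ethnicity = do.call(.categorical_feature, ethnicity),
      religion = do.call(.categorical_feature, religion),
      language = do.call(.categorical_feature, language),
      marital_status = do.call(.categorical_feature, marital_status)
    ),
    numeric = list(age = do.call(.numeric_feature, age),
                   weight = do.call(.numeric_feature, weight)),
    seed = seed, id_prefix = id_prefix
  )
  structure(spec, class = "cohortsuit_population_spec")
}

#' Read a population specification from YAML
#'
#' The YAML mirrors the arguments of [population_spec()]: top-level
#' `n_patients`, `seed`, `id_prefix`, and per-feature blocks with `probs`,
#' `missing_rate`, `unknown_rate` (categorical) or `means`/`sds`/`mix`/
#' `min`/`max`/`missing_rate` (age, weight). Absent blocks keep defaults.
#'
#' @param path Path to a YAML file.
#' @return A `cohortsuit_population_spec`.
#' @export
read_population_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  for (k in c("n_patients", "seed", "id_prefix", "gender", "ethnicity",
              "religion", "language", "marital_status", "age", "weight")) {
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  }
  for (k in c("gender", "ethnicity", "religion", "language",
              "marital_status")) {
    if (!is.null(args[[k]]$probs)) args[[k]]$probs <- unlist(args[[k]]$probs)
  }
  do.call(population_spec, args)
}

.sample_truncated_mixture <- function(n, feat) {
  comp <- sample.int(length(feat$mix), n, replace = TRUE, prob = feat$mix)
  x <- stats::rnorm(n, mean = feat$means[comp], sd = feat$sds[comp])
  pmin(pmax(x, feat$min), feat$max)
}

#' Generate a synthetic patient demographics table
#'
#' Draws `n_patients` independent records from a [population_spec()]:
#' categorical values from the per-feature probabilities, ages and weights
#' from truncated Gaussian mixtures, then injects missingness — absent
#' values (`NA`) at the feature's `missing_rate` and explicit `"UNKNOWN"`
#' designations at its `unknown_rate`. Reproducible for a given seed.
#'
#' @param spec A [population_spec()].
#' @param seed Random seed; defaults to the spec's own.
#' @return Tibble of patient records (one row per patient).
#' @examples
#' pop <- synthetic_population(population_spec(n_patients = 100, seed = 42))
#' @export
synthetic_population <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohortsuit_population_spec"))
  with_seed(seed, {
    n <- spec$n_patients
    out <- tibble::tibble(
      patient_id = sprintf("%s%06d", spec$id_prefix, seq_len(n))
    )
    for (nm in names(spec$numeric)) {
      feat <- spec$numeric[[nm]]
      x <- .sample_truncated_mixture(n, feat)
      if (feat$missing_rate > 0) {
        x[stats::runif(n) < feat$missing_rate] <- NA_real_
      }
      out[[nm]] <- x
    }
    for (nm in names(spec$categorical)) {
      feat <- spec$categorical[[nm]]
      x <- sample(names(feat$probs), n, replace = TRUE, prob = feat$probs)
      u <- stats::runif(n)
      x[u < feat$unknown_rate] <- "UNKNOWN"
      x[u >= feat$unknown_rate &
          u < feat$unknown_rate + feat$missing_rate] <- NA_character_
      out[[nm]] <- x
    }
    out[c("patient_id", "age", "gender", "ethnicity", "weight", "language",
          "religion", "marital_status")]
  })
}

#' Cohort sampling configuration
#'
#' Cohort sizes are drawn from a Gaussian, rounded to the nearest integer
#' and clipped; the defaults (mean 60, SD 13, clipped to \[20, 100\],
#' 100 cohorts) reflect typical Phase II/III single-centre enrolment.
#'
#' @param n_cohorts Number of simulated cohorts.
#' @param size_mean,size_sd Gaussian parameters of the size distribution.
#' @param size_min,size_max Clipping range (integers).
#' @param seed Base random seed; per-cohort sampling seeds derive from it.
#' @return Object of class `cohortsuit_sampling_config`.
#' @export
cohort_sampling_config <- function(n_cohorts = 100, size_mean = 60,
                                   size_sd = 13, size_min = 20,
                                   size_max = 100, seed = NULL) {
  if (n_cohorts < 1) stop("n_cohorts must be at least 1", call. = FALSE)
  if (size_min > size_max) stop("size_min must not exceed size_max",
                                call. = FALSE)
  if (size_sd < 0) stop("size_sd must be non-negative", call. = FALSE)
  structure(list(n_cohorts = as.integer(n_cohorts), size_mean = size_mean,
                 size_sd = size_sd, size_min = as.integer(size_min),
                 size_max = as.integer(size_max), seed = seed),
            class = "cohortsuit_sampling_config")
}

#' Draw simulated cohort sizes
#'
#' Gaussian draws rounded to the nearest integer, then clipped to the
#' configured range.
#'
#' @param config A [cohort_sampling_config()].
#' @param seed Random seed; defaults to the config's.
#' @return Integer vector of `n_cohorts` sizes in
#'   \[`size_min`, `size_max`\].
#' @examples
#' sizes <- sample_cohort_sizes(cohort_sampling_config(seed = 7))
#' mean(sizes); sd(sizes)
#' @export
sample_cohort_sizes <- function(config = cohort_sampling_config(),
                                seed = config$seed) {
  stopifnot(inherits(config, "cohortsuit_sampling_config"))
  with_seed(seed, {
    x <- stats::rnorm(config$n_cohorts, config$size_mean, config$size_sd)
    as.integer(pmin(pmax(round(x), config$size_min), config$size_max))
  })
}

#' Sample one trial cohort without replacement
#'
#' Simple random sampling of `size` distinct patients. Rows are sorted by
#' `patient_id` before drawing so that the cohort depends only on the seed
#' and the set of patients, never on the source table's row ordering.
#'
#' @param population Patient record table.
#' @param size Cohort size; at most the population size.
#' @param seed Random seed.
#' @return Tibble of `size` records.
#' @export
sample_cohort <- function(population, size, seed = NULL) {
  population <- tibble::as_tibble(population)
  if (size > nrow(population)) {
    stop("cohort size ", size, " exceeds the population size ",
         nrow(population), call. = FALSE)
  }
  population <- population[order(population$patient_id), ]
  idx <- with_seed(seed, sample.int(nrow(population), size))
  population[idx, ]
}

#' Run the simulated-cohort validation study
#'
#' Draws `n_cohorts` trial cohorts from a sampling pool (sizes Gaussian,
#' sampling without replacement, per-cohort seeds derived as base seed +
#' cohort index), scores each against the fixed target population, and
#' summarises suitability, coverage and completeness across cohorts together
#' with the unique-selection rate (distinct patients used / total
#' selections, a measure of cohort overlap).
#'
#' @param population Sampling pool of patient records (disjoint from the
#'   target, mirroring a non-case pool scored against a disease cohort).
#' @param target Target population records.
#' @param config A [cohort_sampling_config()].
#' @param schema,policy,weights As in [score_cohort()].
#' @param seed Base seed; defaults to the config's (or 1).
#' @return Object of class `cohortsuit_study`: list with `results` (tibble,
#'   one row per cohort incl. per-feature columns), `summary` (tibble of
#'   min/max/mean/sd per metric), `sizes`, `unique_selection_rate`,
#'   `total_selections`, `target_completeness`.
#' @examples
#' pool <- synthetic_population(population_spec(n_patients = 600, seed = 1))
#' tgt <- synthetic_population(population_spec(n_patients = 300,
#'                                             id_prefix = "T", seed = 2))
#' study <- run_validation_study(pool, tgt,
#'   cohort_sampling_config(n_cohorts = 5, seed = 3))
#' study$summary
#' @export
run_validation_study <- function(population, target,
                                 config = cohort_sampling_config(),
                                 schema = demographic_schema(),
                                 policy = missing_policy(),
                                 weights = weight_config(),
                                 seed = config$seed) {
  if (is.null(seed)) seed <- 1
  pop_assign <- .as_assignments(population, schema, policy)
  target_assign <- .as_assignments(target, schema, policy)
  overlap <- intersect(pop_assign$patient_id, target_assign$patient_id)
  if (length(overlap) > 0) {
    stop("sampling pool and target must be disjoint; shared ids e.g. ",
         overlap[1], call. = FALSE)
  }
  pop_assign <- pop_assign[order(pop_assign$patient_id), ]
  sizes <- sample_cohort_sizes(config, seed = seed)

  rows <- vector("list", config$n_cohorts)
  selected <- vector("list", config$n_cohorts)
  for (i in seq_len(config$n_cohorts)) {
    idx <- with_seed(seed + i, sample.int(nrow(pop_assign), sizes[i]))
    cid <- sprintf("C-%03d", i)
    res <- tryCatch(
      score_assignments(pop_assign[idx, ], target_assign,
                        weights = weights, cohort_id = cid),
      error = function(e) stop("cohort ", cid, ": ", conditionMessage(e),
                               call. = FALSE))
    rows[[i]] <- as_tibble_result(res)
    selected[[i]] <- pop_assign$patient_id[idx]
  }
  selected <- unlist(selected)
  results <- do.call(rbind, rows)
  summary <- tibble::tibble(metric = c("suitability", "coverage",
                                       "completeness"),
                            min = NA_real_, max = NA_real_,
                            mean = NA_real_, sd = NA_real_)
  for (j in seq_len(nrow(summary))) {
    x <- results[[summary$metric[j]]]
    summary$min[j] <- min(x); summary$max[j] <- max(x)
    summary$mean[j] <- mean(x)
    summary$sd[j] <- if (length(x) > 1) stats::sd(x) else 0
  }
  structure(list(
    results = results,
    summary = summary,
    sizes = sizes,
    total_selections = length(selected),
    unique_selection_rate = length(unique(selected)) / length(selected),
    target_completeness = completeness_profile(target_assign),
    config = config, weights = weights, seed = seed
  ), class = "cohortsuit_study")
}

#' @export
print.cohortsuit_study <- function(x, ...) {
  cat(sprintf("<cohortsuit study> %d cohorts (sizes %d-%d, mean %.1f)\n",
              length(x$sizes), min(x$sizes), max(x$sizes), mean(x$sizes)))
  cat(sprintf("  unique selection rate %.1f%% (%d selections)\n",
              100 * x$unique_selection_rate, x$total_selections))
  s <- x$summary
  for (j in seq_len(nrow(s))) {
    cat(sprintf("  %-12s mean %.1f (sd %.2f), range %.1f-%.1f\n",
                s$metric[j], s$mean[j], s$sd[j], s$min[j], s$max[j]))
  }
  invisible(x)
}
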