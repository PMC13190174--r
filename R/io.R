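# CSV readers/writers, radar-plot data export, run manifests, and the
# command-line entry point.

#' Default column-name map
#'
#' Maps the canonical record fields to the column names expected in an
#' input CSV; override entries to read tables with different headers.
#'
#' @return Named character vector (field -> column name).
#' @export
default_column_map <- function() {
  c(patient_id = "patient_id", age = "age", gender = "gender",
    ethnicity = "ethnicity", weight = "weight", language = "language",
    religion = "religion", marital_status = "marital_status")
}

#' Read a patient demographics CSV
#'
#' Comma-separated, UTF-8, header row required. Empty cells are read as
#' missing; unparseable numeric cells (age, weight) become missing with a
#' warning reporting the count. Columns are renamed to the canonical fields
#' via the column map.
#'
#' @param path Path to the CSV file.
#' @param column_map Field -> column name map; see [default_column_map()].
#' @return Tibble of patient records.
#' @export
read_demographics_csv <- function(path, column_map = default_column_map()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) == 0) stop("empty input: ", path, call. = FALSE)
  absent <- setdiff(unname(column_map), names(raw))
  if (length(absent) > 0) {
    stop("missing required column(s) in ", path, ": ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(.rows = nrow(raw))
  for (field in names(column_map)) {
    col <- raw[[column_map[[field]]]]
    col[!nzchar(trimws(col))] <- NA_character_
    if (field %in% c("age", "weight")) {
      num <- suppressWarnings(as.numeric(col))
      bad <- sum(!is.na(col) & is.na(num))
      if (bad > 0) {
        warning(bad, " unparseable ", field, " value(s) in ", basename(path),
                " treated as missing", call. = FALSE)
      }
      out[[field]] <- num
    } else {
      out[[field]] <- col
    }
  }
  out
}

#' Write patient records as CSV
#'
#' Writes the same dialect [read_demographics_csv()] reads: missing values
#' become empty cells, numerics keep full precision.
#'
#' @param records Patient record table.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_demographics_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Export scoring results
#'
#' Writes a per-cohort CSV (one row per cohort, per-feature columns at full
#' precision) and, if `json` is given, the same content plus the study
#' summary as JSON.
#'
#' @param x A `cohortsuit_result`, list thereof, or `cohortsuit_study`.
#' @param csv,json Output paths (either may be `NULL`).
#' @return The results tibble, invisibly.
#' @export
export_results <- function(x, csv = NULL, json = NULL) {
  if (inherits(x, "cohortsuit_result")) x <- list(x)
  if (inherits(x, "cohortsuit_study")) {
    results <- x$results
    summary <- x$summary
  } else {
    results <- do.call(rbind, lapply(x, as_tibble_result))
    summary <- NULL
  }
  if (!is.null(csv)) {
    utils::write.csv(as.data.frame(results), csv, row.names = FALSE, na = "")
  }
  if (!is.null(json)) {
    payload <- list(results = results)
    if (!is.null(summary)) payload$summary <- summary
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(results)
}

#' Long-format radar-plot data
#'
#' Builds the per-feature profile table behind the radar figures: for every
#' entity (the target population plus each cohort) and every feature, rows
#' for the three metrics. The target's coverage is 100 for every feature by
#' definition (perfect self-similarity); its completeness is its own
#' profile; the per-feature suitability composite mixes the two with the
#' aggregation weights.
#'
#' @param results A `cohortsuit_study`, `cohortsuit_result`, or list of
#'   results.
#' @param target_completeness Named per-feature completeness vector for the
#'   target (a study carries its own; see [completeness_profile()]).
#' @param weights A [weight_config()] supplying the aggregation mix.
#' @return Tibble with columns `entity`, `feature`, `metric`
#'   (`coverage` / `completeness` / `suitability`), `value`.
#' @export
export_radar_data <- function(results, target_completeness = NULL,
                              weights = weight_config()) {
  if (inherits(results, "cohortsuit_study")) {
    if (is.null(target_completeness)) {
      target_completeness <- results$target_completeness
    }
    tab <- results$results
  } else {
    if (inherits(results, "cohortsuit_result")) results <- list(results)
    tab <- do.call(rbind, lapply(results, as_tibble_result))
  }
  if (nrow(tab) == 0) stop("no results to export", call. = FALSE)
  if (is.null(target_completeness)) {
    stop("target_completeness is required when results carry no study target",
         call. = FALSE)
  }
  feats <- feature_names()
  wc <- weights$coverage_weight
  wk <- weights$completeness_weight

  entity_rows <- function(entity, cov, comp) {
    tibble::tibble(
      entity = entity,
      feature = rep(feats, 3),
      metric = rep(c("coverage", "completeness", "suitability"),
                   each = length(feats)),
      value = c(cov, comp, wc * cov + wk * comp)
    )
  }
  out <- list(entity_rows("target", rep(100, length(feats)),
                          unname(target_completeness[feats])))
  for (i in seq_len(nrow(tab))) {
    cov <- as.numeric(tab[i, paste0("coverage.", feats)])
    comp <- as.numeric(tab[i, paste0("completeness.", feats)])
    out[[i + 1]] <- entity_rows(tab$cohort_id[i], cov, comp)
  }
  do.call(rbind, out)
}

#' Render a radar-style profile plot
#'
#' Optional presentation layer over [export_radar_data()] (the data export
#' is the contract): a polar line plot of one metric's per-feature profile
#' for each entity. Requires ggplot2.
#'
#' @param radar_data Table from [export_radar_data()].
#' @param metric One of `"coverage"`, `"completeness"`, `"suitability"`.
#' @return A ggplot object.
#' @export
plot_radar <- function(radar_data, metric = c("coverage", "completeness",
                                              "suitability")) {
  metric <- match.arg(metric)
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_radar requires ggplot2", call. = FALSE)
  }
  d <- radar_data[radar_data$metric == metric, ]
  d$feature <- factor(d$feature, levels = feature_names())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature, y = .data$value,
                                  group = .data$entity,
                                  colour = .data$entity)) +
    ggplot2::geom_polygon(fill = NA, linewidth = 0.7) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_polar() +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(title = sprintf("Per-feature %s profile", metric),
                  x = NULL, y = "%") +
    ggplot2::theme_minimal()
}

#' Write a run manifest
#'
#' Records everything needed to regenerate an output directory: the
#' resolved configuration, seed, package version and an MD5 of the
#' serialized configuration.
#'
#' @param dir Output directory.
#' @param config List of resolved configuration values.
#' @param seed The run's base seed.
#' @return Path to the manifest, invisibly.
#' @export
write_manifest <- function(dir, config, seed = NULL) {
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  manifest <- list(
    package = "cohortsuit",
    version = as.character(utils::packageVersion("cohortsuit")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_file = "config.json",
    config_md5 = unname(tools::md5sum(cfg_path))
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
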