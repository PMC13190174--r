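# Demographic schema, binning rules, missing-value semantics and ethnicity
# consolidation. All category comparison is case-insensitive on upper-cased,
# whitespace-trimmed labels.

#' Demographic feature names
#'
#' The seven demographic dimensions assessed by the framework, in canonical
#' (weight-priority) order.
#'
#' @return Character vector of the seven feature names.
#' @export
feature_names <- function() {
  c("AGE_GROUP", "GENDER", "ETHNICITY", "WEIGHT_GROUP",
    "RELIGION", "LANGUAGE", "MARITAL_STATUS")
}

# Age bins partition [0, Inf); half-open [lower, upper) convention so that
# boundary ages (1, 18, 40, 65, 80) fall in the upper group.
.age_breaks <- c(0, 1, 18, 40, 65, 80, Inf)
.age_labels <- c("Neonate/Infant", "Child/Adolescent", "Young Adult",
                 "Middle-aged", "Older Adult", "Elderly")

# Weight bins partition (0, Inf); same half-open convention (50 kg -> Normal).
.weight_breaks <- c(0, 50, 70, 90, 120, Inf)
.weight_labels <- c("Underweight", "Normal", "Overweight", "Obese",
                    "Severely Obese")

#' Demographic schema
#'
#' Builds the seven-feature schema: two binned-numeric features (age in years
#' binned into six clinically motivated groups, weight in kg binned into five
#' dosing-relevant groups) and five categorical features whose category
#' inventories are taken as observed in the data.
#'
#' @return A list of class `cohortsuit_schema`; one element per feature with
#'   `name`, `kind` (`"binned"` or `"categorical"`), `source` (the raw column
#'   it is derived from) and, for binned features, the fixed `categories`.
#' @examples
#' names(demographic_schema())
#' @export
demographic_schema <- function() {
  schema <- list(
    AGE_GROUP      = list(name = "AGE_GROUP", kind = "binned",
                          source = "age", categories = .age_labels),
    GENDER         = list(name = "GENDER", kind = "categorical",
                          source = "gender", categories = NULL),
    ETHNICITY      = list(name = "ETHNICITY", kind = "categorical",
                          source = "ethnicity", categories = NULL),
    WEIGHT_GROUP   = list(name = "WEIGHT_GROUP", kind = "binned",
                          source = "weight", categories = .weight_labels),
    RELIGION       = list(name = "RELIGION", kind = "categorical",
                          source = "religion", categories = NULL),
    LANGUAGE       = list(name = "LANGUAGE", kind = "categorical",
                          source = "language", categories = NULL),
    MARITAL_STATUS = list(name = "MARITAL_STATUS", kind = "categorical",
                          source = "marital_status", categories = NULL)
  )
  structure(schema, class = "cohortsuit_schema")
}

#' Missing-value policy
#'
#' Defines which raw values are counted as incomplete. Both absent values
#' (`NA`, empty string) and explicit unknown designations are flagged;
#' matching is case-insensitive and whitespace-trimmed.
#'
#' @param unknown_designations Character vector of values treated as
#'   incomplete. The defaults cover the usual EHR conventions
#'   ("UNKNOWN", "PATIENT DECLINED", "UNABLE TO OBTAIN" and common variants).
#' @return Object of class `cohortsuit_missing_policy`.
#' @export
missing_policy <- function(unknown_designations = c(
  "UNKNOWN", "UNKNOWN/NOT SPECIFIED", "UNKNOWN (DEFAULT)",
  "PATIENT DECLINED", "PATIENT DECLINED TO ANSWER",
  "UNABLE TO OBTAIN", "NOT SPECIFIED", "")) {
  stopifnot(is.character(unknown_designations))
  norm <- unique(toupper(trimws(unknown_designations)))
  if (!all(c("UNKNOWN", "PATIENT DECLINED", "UNABLE TO OBTAIN", "") %in% norm)) {
    stop("missing policy must include at least 'UNKNOWN', 'PATIENT DECLINED', ",
         "'UNABLE TO OBTAIN' and the empty string", call. = FALSE)
  }
  structure(list(unknown_designations = norm),
            class = "cohortsuit_missing_policy")
}

#' Test whether raw values are incomplete
#'
#' @param value Vector of raw cell values (character or numeric).
#' @param policy A [missing_policy()].
#' @return Logical vector: `TRUE` where the value is absent or matches an
#'   unknown designation (case-insensitively, after trimming).
#' @examples
#' is_missing(c("Male", "unknown ", NA, ""), missing_policy())
#' @export
is_missing <- function(value, policy = missing_policy()) {
  stopifnot(inherits(policy, "cohortsuit_missing_policy"))
  if (is.numeric(value)) return(is.na(value))
  is.na(value) | toupper(trimws(as.character(value))) %in%
    policy$unknown_designations
}

#' Assign ages to clinical age groups
#'
#' Six groups: Neonate/Infant (0-1), Child/Adolescent (1-18), Young Adult
#' (18-40), Middle-aged (40-65), Older Adult (65-80), Elderly (80+), all in
#' years. Intervals are half-open `[lower, upper)`, so a boundary age belongs
#' to the upper group (age 18 is Young Adult, age 65 is Older Adult).
#'
#' @param age Numeric vector of ages in years; `NA` passes through as `NA`.
#' @return Character vector of age-group labels.
#' @examples
#' bin_age(c(0.5, 17, 18, 45, 80))
#' @export
bin_age <- function(age) {
  if (!is.numeric(age)) stop("age must be numeric", call. = FALSE)
  if (any(age < 0, na.rm = TRUE)) {
    stop("age must be non-negative", call. = FALSE)
  }
  as.character(cut(age, breaks = .age_breaks, labels = .age_labels,
                   right = FALSE, include.lowest = TRUE))
}

#' Assign body weights to dosing-relevant weight groups
#'
#' Five groups in kg: Underweight (<50), Normal (50-70), Overweight (70-90),
#' Obese (90-120), Severely Obese (120+). Intervals are half-open
#' `[lower, upper)`: exactly 50 kg is Normal, exactly 120 kg Severely Obese.
#'
#' @param weight Numeric vector of body weights in kg; `NA` passes through.
#' @return Character vector of weight-group labels.
#' @examples
#' bin_weight(c(49.9, 50, 85, 120))
#' @export
bin_weight <- function(weight) {
  if (!is.numeric(weight)) stop("weight must be numeric", call. = FALSE)
  if (any(weight <= 0, na.rm = TRUE)) {
    stop("weight must be positive", call. = FALSE)
  }
  as.character(cut(weight, breaks = .weight_breaks, labels = .weight_labels,
                   right = FALSE))
}

#' Default ethnicity consolidation mapping
#'
#' Consolidates the many raw EHR ethnicity labels into seven major groups:
#' White, Black/African American, Hispanic/Latino, Asian, Other, Multiple,
#' Unknown. The default is keyed on the label-prefix conventions used by
#' MIMIC-style records ("WHITE - RUSSIAN", "ASIAN - CHINESE", ...): a raw
#' label inherits the group of its head word. Labels already equal to a group
#' map to themselves, so consolidation is idempotent.
#'
#' @return Named list with `prefixes` (named character: regex prefix ->
#'   group) and `exact` (named character: exact upper-cased label -> group).
#' @export
default_ethnicity_map <- function() {
  list(
    prefixes = c(
      "WHITE"            = "White",
      "BLACK"            = "Black/African American",
      "HISPANIC"         = "Hispanic/Latino",
      "LATINO"           = "Hispanic/Latino",
      "ASIAN"            = "Asian",
      "MULTI"            = "Multiple",
      "UNKNOWN"          = "Unknown",
      "PATIENT DECLINED" = "Unknown",
      "UNABLE TO OBTAIN" = "Unknown",
      "AMERICAN INDIAN"  = "Other",
      "NATIVE HAWAIIAN"  = "Other",
      "MIDDLE EASTERN"   = "Other",
      "PORTUGUESE"       = "Other",
      "SOUTH AMERICAN"   = "Other",
      "CARIBBEAN ISLAND" = "Other",
      "OTHER"            = "Other"
    ),
    exact = c(
      "BLACK/AFRICAN AMERICAN" = "Black/African American",
      "HISPANIC/LATINO"        = "Hispanic/Latino",
      "MULTIPLE"               = "Multiple",
      "MULTI RACE ETHNICITY"   = "Multiple",
      "NOT SPECIFIED"          = "Unknown"
    )
  )
}

#' Consolidate raw ethnicity labels into seven major groups
#'
#' @param raw_label Character vector of raw labels.
#' @param mapping Mapping as returned by [default_ethnicity_map()] or read
#'   from a YAML/JSON config via [read_ethnicity_map()].
#' @param fallback Optional group assigned to labels the mapping does not
#'   cover; with no fallback an unmapped label is an error listing the label.
#' @return Character vector of group labels; `NA` input stays `NA`.
#' @examples
#' consolidate_ethnicity(c("WHITE - RUSSIAN", "ASIAN", "UNKNOWN/NOT SPECIFIED"))
#' @export
consolidate_ethnicity <- function(raw_label, mapping = default_ethnicity_map(),
                                  fallback = NULL) {
  groups <- c("White", "Black/African American", "Hispanic/Latino", "Asian",
              "Other", "Multiple", "Unknown")
  lab <- toupper(trimws(as.character(raw_label)))
  out <- rep(NA_character_, length(lab))
  out[is.na(raw_label)] <- NA_character_

  exact_keys <- toupper(names(mapping$exact))
  for (i in seq_along(lab)) {
    if (is.na(raw_label[i])) next
    # identity on the seven head groups keeps consolidation idempotent
    hit <- match(lab[i], toupper(groups))
    if (!is.na(hit)) { out[i] <- groups[hit]; next }
    hit <- match(lab[i], exact_keys)
    if (!is.na(hit)) { out[i] <- unname(mapping$exact[hit]); next }
    pre <- which(startsWith(lab[i], names(mapping$prefixes)))
    if (length(pre) > 0) {
      # longest prefix wins ("UNABLE TO OBTAIN" before "UN...")
      pre <- pre[which.max(nchar(names(mapping$prefixes))[pre])]
      out[i] <- unname(mapping$prefixes[pre])
      next
    }
    if (!is.null(fallback)) { out[i] <- fallback; next }
    stop("unmapped ethnicity label: '", raw_label[i],
         "' (configure a mapping entry or a fallback group)", call. = FALSE)
  }
  out
}

#' Convert patient records into per-feature category assignments
#'
#' Turns a raw demographics table (one row per patient) into a 7-feature
#' assignment table: binned-numeric features pass through [bin_age()] /
#' [bin_weight()], ethnicity is consolidated, and any value flagged by the
#' missing policy becomes `NA` (the MISSING marker). Categorical labels are
#' upper-cased and trimmed so that distributions compare like with like.
#'
#' @param records Tibble/data.frame of patient records with columns
#'   `patient_id`, `age`, `gender`, `ethnicity`, `weight`, `language`,
#'   `religion`, `marital_status` (any but `patient_id` may be missing).
#' @param schema A [demographic_schema()].
#' @param policy A [missing_policy()].
#' @param ethnicity_map Mapping passed to [consolidate_ethnicity()].
#' @param ethnicity_fallback Optional fallback group for unmapped labels.
#' @return Tibble with `patient_id` plus one column per feature, values being
#'   category labels or `NA` for missing.
#' @export
featurize <- function(records, schema = demographic_schema(),
                      policy = missing_policy(),
                      ethnicity_map = default_ethnicity_map(),
                      ethnicity_fallback = NULL) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) stop("empty cohort: no patient records", call. = FALSE)
  if (!"patient_id" %in% names(records)) {
    stop("records must carry a 'patient_id' column", call. = FALSE)
  }
  ids <- as.character(records$patient_id)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("patient_id must be non-empty for every record", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("patient_id must be unique within a table", call. = FALSE)
  }

  out <- tibble::tibble(patient_id = ids)
  for (fs in schema) {
    col <- records[[fs$source]]
    if (is.null(col)) col <- rep(NA, nrow(records))
    if (fs$kind == "binned") {
      num <- suppressWarnings(as.numeric(col))
      assigned <- rep(NA_character_, length(num))
      ok <- !is.na(num)
      if (any(ok)) {
        assigned[ok] <- if (fs$name == "AGE_GROUP") bin_age(num[ok]) else
          bin_weight(num[ok])
      }
    } else {
      miss <- is_missing(col, policy)
      assigned <- toupper(trimws(as.character(col)))
      assigned[miss] <- NA_character_
      if (fs$name == "ETHNICITY") {
        valid <- !is.na(assigned)
        grp <- consolidate_ethnicity(assigned[valid], ethnicity_map,
                                     fallback = ethnicity_fallback)
        # consolidated Unknowns count as incomplete, like explicit designations
        grp[is_missing(grp, policy)] <- NA_character_
        assigned[valid] <- grp
      }
    }
    out[[fs$name]] <- assigned
  }
  out
}
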