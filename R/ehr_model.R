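#' Cohort inclusion configuration
#'
#' @param min_stay_hours Minimum hospital length of stay, in hours. Encounters
#'   shorter than this are excluded (default 1 hour).
#' @param excluded_encounter_contexts Encounter contexts excluded from the
#'   cohort (endoscopy, direct psychiatric admissions, ED transfers to labor
#'   and delivery).
#' @param prediction_cadence_minutes Expected spacing of model scores.
#' @param pre_arrival_lookback_hours Events up to this many hours before
#'   arrival are accepted into the stream; with the default 0, only events at
#'   or after arrival contribute to phenotyping criteria.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(min_stay_hours = 1,
                          excluded_encounter_contexts = c(
                            "endoscopy", "psychiatric_direct_admission",
                            "ed_to_labor_and_delivery"),
                          prediction_cadence_minutes = 15L,
                          pre_arrival_lookback_hours = 0) {
  stopifnot(min_stay_hours > 0, prediction_cadence_minutes > 0,
            pre_arrival_lookback_hours >= 0)
  structure(list(min_stay_hours = min_stay_hours,
                 excluded_encounter_contexts = excluded_encounter_contexts,
                 prediction_cadence_minutes = as.integer(prediction_cadence_minutes),
                 pre_arrival_lookback_hours = pre_arrival_lookback_hours),
            class = "cohort_config")
}

#' Read a cohort configuration from JSON
#' @param path Path to a JSON file with any subset of the [cohort_config()]
#'   fields.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(cohort_config, raw)
}

read_delim_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  na.strings = c("NA", ""))
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("schema error in %s: missing column(s) %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

parse_time_column <- function(x, what) {
  t <- parse_timestamp(x)
  bad <- which(is.na(t) & !is.na(x))
  if (length(bad) > 0) {
    stop(sprintf("unparseable timestamp in %s at data row(s) %s", what,
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  }
  t
}

#' Read a clinical event table
#'
#' Reads a delimited event table (one row per timestamped observation or
#' action) with columns `encounter_id, patient_id, time, kind, concept,
#' value, antibiotic_name`. Timestamps must be ISO 8601. Unknown concept
#' codes are rejected with an error naming the offending codes; events are
#' returned sorted by `(encounter_id, time)`.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(time = "obs_ts")`.
#' @param extra_concepts Additional concept codes to admit beyond the fixed
#'   vocabulary of [concept_registry()].
#' @return A data.frame of events.
#' @export
read_events <- function(path, schema = NULL, extra_concepts = character()) {
  df <- read_delim_table(path)
  if (!is.null(schema)) {
    idx <- match(unname(schema), names(df))
    if (anyNA(idx)) {
      stop(sprintf("schema error: mapped column(s) %s not found in file",
                   paste(schema[is.na(idx)], collapse = ", ")), call. = FALSE)
    }
    names(df)[idx] <- names(schema)
  }
  require_columns(df, c("encounter_id", "patient_id", "time", "kind", "concept"),
                  "events")
  if (is.null(df$value)) df$value <- NA_real_
  if (is.null(df$antibiotic_name)) df$antibiotic_name <- NA_character_
  df$time <- parse_time_column(df$time, "events")
  df$value <- as.numeric(df$value)

  known <- c(concept_registry()$concept, extra_concepts)
  unknown <- setdiff(unique(df$concept), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown concept code(s): %s",
                 paste(sort(unknown), collapse = ", ")), call. = FALSE)
  }
  meas <- df$concept %in% measurement_concepts()
  if (any(meas & is.na(df$value))) {
    stop("measurement events without a value present", call. = FALSE)
  }
  if (any(!meas & !is.na(df$value) & !df$concept %in% extra_concepts)) {
    stop("action events must not carry a value", call. = FALSE)
  }
  if (any(df$concept == "iv_antibiotic_admin" & is.na(df$antibiotic_name))) {
    stop("iv_antibiotic_admin events require antibiotic_name", call. = FALSE)
  }
  df <- df[order(df$encounter_id, df$time), , drop = FALSE]
  rownames(df) <- NULL
  df[, c("encounter_id", "patient_id", "time", "kind", "concept", "value",
         "antibiotic_name")]
}

#' Write a clinical event table
#' @param events Event data.frame as returned by [read_events()].
#' @param path Output CSV path.
#' @export
write_events <- function(events, path) {
  out <- events
  out$time <- format_timestamp(out$time)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an encounter table
#'
#' @param path Path to a CSV with columns `encounter_id, patient_id,
#'   arrival_time, discharge_time, encounter_type, hospital_type, age_years,
#'   sex, race, ethnicity, esi, died_in_hospital` (and optionally `context`).
#' @return A data.frame of encounters.
#' @export
read_encounters <- function(path) {
  df <- read_delim_table(path)
  require_columns(df, c("encounter_id", "patient_id", "arrival_time",
                        "discharge_time", "encounter_type"), "encounters")
  df$arrival_time <- parse_time_column(df$arrival_time, "encounters")
  df$discharge_time <- parse_time_column(df$discharge_time, "encounters")
  if (any(df$discharge_time <= df$arrival_time)) {
    stop("encounters with discharge_time <= arrival_time", call. = FALSE)
  }
  if (!is.null(df$died_in_hospital)) {
    df$died_in_hospital <- as.logical(df$died_in_hospital)
  }
  df[order(df$encounter_id), , drop = FALSE]
}

#' Write an encounter table
#' @param encounters Encounter data.frame.
#' @param path Output CSV path.
#' @export
write_encounters <- function(encounters, path) {
  out <- encounters
  out$arrival_time <- format_timestamp(out$arrival_time)
  out$discharge_time <- format_timestamp(out$discharge_time)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a prediction table
#' @param path Path to a CSV with columns `encounter_id, time, score`.
#' @return A data.frame of predictions sorted by `(encounter_id, time)`.
#' @export
read_predictions <- function(path) {
  df <- read_delim_table(path)
  require_columns(df, c("encounter_id", "time", "score"), "predictions")
  df$time <- parse_time_column(df$time, "predictions")
  df$score <- as.numeric(df$score)
  if (any(df$score < 0 | df$score > 100, na.rm = TRUE)) {
    stop("prediction scores must lie in [0, 100]", call. = FALSE)
  }
  df <- df[order(df$encounter_id, df$time), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a prediction table
#' @param predictions Prediction data.frame.
#' @param path Output CSV path.
#' @export
write_predictions <- function(predictions, path) {
  out <- predictions
  out$time <- format_timestamp(out$time)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Apply cohort inclusion filters
#'
#' Excludes encounters with a hospital stay shorter than the configured
#' minimum and encounters in excluded contexts. Every input encounter is
#' accounted for: `nrow(input) == nrow(included) + sum(exclusion_tally)`.
#'
#' @param encounters Encounter data.frame.
#' @param config A [cohort_config()].
#' @return A list with `included` (data.frame) and `exclusion_tally`
#'   (named integer vector of counts by reason).
#' @export
apply_inclusion_filters <- function(encounters, config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  stay <- hours_between(encounters$arrival_time, encounters$discharge_time)
  if (any(is.na(stay)) || any(stay <= 0)) {
    stop("encounters must have valid arrival/discharge times", call. = FALSE)
  }
  context <- encounters$context %||% rep(NA_character_, nrow(encounters))
  excl_context <- !is.na(context) &
    context %in% config$excluded_encounter_contexts
  excl_short <- !excl_context & stay < config$min_stay_hours

  tally <- c(excluded_context = sum(excl_context),
             short_stay = sum(excl_short))
  tally <- tally[tally > 0]
  included <- encounters[!excl_context & !excl_short, , drop = FALSE]
  rownames(included) <- NULL
  stopifnot(nrow(encounters) == nrow(included) + sum(tally))
  list(included = included, exclusion_tally = tally)
}

#' Incidence (or any case proportion) as a printed percentage
#'
#' Computes `100 * case_count / cohort_count`, rounded half-up to one
#' decimal, matching the display convention of clinical tables. Also used
#' for case-mortality proportions and flagged fractions.
#'
#' @param case_count Number of cases (0 <= case_count <= cohort_count).
#' @param cohort_count Cohort size (> 0).
#' @return Percentage rounded to one decimal.
#' @export
incidence <- function(case_count, cohort_count) {
  if (any(cohort_count <= 0)) stop("cohort_count must be positive", call. = FALSE)
  if (any(case_count < 0 | case_count > cohort_count)) {
    stop("case_count must lie in [0, cohort_count]", call. = FALSE)
  }
  round_half_up(100 * case_count / cohort_count, 1)
}
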