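#' Build encounter-level evaluation instances
#'
#' One instance per encounter, scored by the highest model score strictly
#' before the sepsis time zero (cases) or hospital discharge. Encounters
#' with no eligible prediction are flagged (`no_eligible_prediction`) and
#' carry an `NA` score; metric functions drop them, and their count is
#' reported in the `n_no_eligible` attribute.
#'
#' @param predictions Prediction data.frame (`encounter_id`, `time`,
#'   `score`), sorted by time within encounter.
#' @param labels Label data.frame (`encounter_id`, `definition`, `is_case`,
#'   `time_zero`) as from [phenotype_cohort()] or a truth table.
#' @param encounters Encounter data.frame.
#' @param definition Which definition's labels to use.
#' @return A data.frame of encounter instances carrying the encounter's
#'   subgroup fields.
#' @export
build_encounter_instances <- function(predictions, labels, encounters,
                                      definition) {
  lab <- labels[labels$definition == definition, , drop = FALSE]
  idx <- match(encounters$encounter_id, lab$encounter_id)
  if (anyNA(idx)) {
    stop("join error: encounters without labels for definition ", definition,
         call. = FALSE)
  }
  lab <- lab[idx, , drop = FALSE]
  cutoff <- as.numeric(encounters$discharge_time)
  has_t0 <- lab$is_case & !is.na(lab$time_zero)
  cutoff[has_t0] <- pmin(cutoff[has_t0], as.numeric(lab$time_zero[has_t0]))

  pi <- match(predictions$encounter_id, encounters$encounter_id)
  ok <- !is.na(pi) & as.numeric(predictions$time) < cutoff[pi]
  mx <- tapply(predictions$score[ok],
               factor(predictions$encounter_id[ok],
                      levels = encounters$encounter_id), max)
  out <- encounters
  out$definition <- definition
  out$label <- lab$is_case
  out$time_zero <- lab$time_zero
  out$max_score_pre_t0 <- as.numeric(mx[encounters$encounter_id])
  out$no_eligible_prediction <- is.na(out$max_score_pre_t0)
  rownames(out) <- NULL
  attr(out, "n_no_eligible") <- sum(out$no_eligible_prediction)
  out
}

#' Build prediction-level (horizon) instances
#'
#' Each prediction becomes an instance labeled positive when the encounter's
#' time zero falls within `horizon_hours` after the prediction. By default,
#' predictions at or after time zero are excluded for case encounters (a
#' score emitted at or after recognition is not advance warning); set
#' `include_post_t0 = TRUE` to keep and label them positive instead.
#' Non-case encounters contribute all their predictions as negatives.
#'
#' @inheritParams build_encounter_instances
#' @param horizon_hours Prediction horizon (e.g. 8 or 24).
#' @param unit_intervals Optional unit-interval table (`encounter_id`,
#'   `unit`, `start`, `end`); when given, each instance carries
#'   `unit_at_prediction` resolved by half-open interval containment.
#' @param include_post_t0 Keep case predictions at/after time zero, labeled
#'   positive.
#' @return A data.frame of horizon instances.
#' @export
build_horizon_instances <- function(predictions, labels, encounters,
                                    horizon_hours, unit_intervals = NULL,
                                    include_post_t0 = FALSE) {
  stopifnot(horizon_hours > 0)
  lab <- labels[labels$definition == labels$definition[1], , drop = FALSE]
  if (length(unique(labels$definition)) > 1) {
    stop("labels must be filtered to a single definition", call. = FALSE)
  }
  li <- match(predictions$encounter_id, lab$encounter_id)
  if (anyNA(li)) stop("join error: predictions without labels", call. = FALSE)
  t0 <- as.numeric(lab$time_zero)[li]
  is_case <- lab$is_case[li]
  tnum <- as.numeric(predictions$time)
  keep <- !is_case | include_post_t0 | tnum < t0
  gap_h <- (t0 - tnum) / 3600
  label <- is_case & ((gap_h <= horizon_hours & gap_h > 0) |
                        (include_post_t0 & gap_h <= 0))
  out <- data.frame(encounter_id = predictions$encounter_id,
                    prediction_time = predictions$time,
                    score = predictions$score,
                    horizon_hours = horizon_hours,
                    label = label, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  ei <- match(out$encounter_id, encounters$encounter_id)
  out$patient_id <- encounters$patient_id[ei]
  if (!is.null(unit_intervals)) {
    key <- seq_len(nrow(out))
    m <- merge(data.frame(key = key, encounter_id = out$encounter_id,
                          t = as.numeric(out$prediction_time),
                          stringsAsFactors = FALSE),
               unit_intervals, by = "encounter_id")
    m <- m[m$t >= as.numeric(m$start) & m$t < as.numeric(m$end), , drop = FALSE]
    out$unit_at_prediction <- NA_character_
    out$unit_at_prediction[m$key] <- m$unit
  }
  rownames(out) <- NULL
  out
}

#' Censor predictions to before sepsis-related clinical actions
#'
#' Keeps, per encounter, only the predictions strictly before the earliest
#' event among the chosen action concepts (ordering of lactic acid, blood
#' cultures, or IV antibiotic administration). Encounters without any such
#' action keep all their predictions.
#'
#' @param predictions Prediction data.frame.
#' @param events Event data.frame.
#' @param action_concepts Nonempty subset of [sepsis_action_concepts()].
#' @return The censored prediction data.frame (a subset of the input), with
#'   attribute `n_fully_censored` counting encounters left without any
#'   prediction.
#' @export
censor_before_actions <- function(predictions, events,
                                  action_concepts = sepsis_action_concepts()) {
  if (length(action_concepts) == 0 ||
      !all(action_concepts %in% sepsis_action_concepts())) {
    stop("action_concepts must be a nonempty subset of sepsis_action_concepts()",
         call. = FALSE)
  }
  act <- events[events$concept %in% action_concepts, , drop = FALSE]
  first_act <- tapply(as.numeric(act$time), act$encounter_id, min)
  cutoff <- first_act[predictions$encounter_id]
  keep <- is.na(cutoff) | as.numeric(predictions$time) < cutoff
  out <- predictions[keep, , drop = FALSE]
  rownames(out) <- NULL
  had <- unique(predictions$encounter_id)
  attr(out, "n_fully_censored") <- length(setdiff(had, unique(out$encounter_id)))
  out
}

#' First threshold crossing of a single encounter's score stream
#'
#' @param predictions Predictions of one encounter.
#' @param threshold Score threshold in \[0, 100\].
#' @return Time of the first prediction with score >= threshold, or `NA`.
#' @export
first_crossing <- function(predictions, threshold) {
  stopifnot(threshold >= 0, threshold <= 100)
  hit <- predictions$time[predictions$score >= threshold]
  if (length(hit) == 0) .na_time() else min(hit)
}

#' Lead times between threshold crossing and time zero
#'
#' For each case encounter, the lead time is the gap between the first
#' prediction reaching the threshold and the definition's time zero, for
#' crossings that precede time zero. Cases first detected at or after time
#' zero are tallied separately as late detections; never-crossing cases as
#' undetected.
#'
#' @param predictions Prediction data.frame.
#' @param labels Label data.frame filtered to one definition.
#' @param threshold Score threshold in \[0, 100\].
#' @return A list with `records` (one row per case:
#'   `encounter_id, threshold, first_crossing_time, lead_hours`) and
#'   `summary` (median and IQR of defined leads plus tallies).
#' @export
lead_times <- function(predictions, labels, threshold) {
  stopifnot(threshold >= 0, threshold <= 100)
  if (length(unique(labels$definition)) > 1) {
    stop("labels must be filtered to a single definition", call. = FALSE)
  }
  cases <- labels[labels$is_case, , drop = FALSE]
  hit <- predictions[predictions$score >= threshold, , drop = FALSE]
  first_hit <- tapply(as.numeric(hit$time), hit$encounter_id, min)
  cross <- first_hit[cases$encounter_id]
  t0 <- as.numeric(cases$time_zero)
  lead <- (t0 - cross) / 3600
  early <- !is.na(lead) & lead > 0
  late <- !is.na(lead) & lead <= 0
  records <- data.frame(
    encounter_id = cases$encounter_id, threshold = threshold,
    first_crossing_time = as.POSIXct(as.numeric(cross), origin = "1970-01-01",
                                     tz = "UTC"),
    lead_hours = ifelse(early, lead, NA_real_), stringsAsFactors = FALSE)
  qs <- if (any(early)) stats::quantile(lead[early], c(0.25, 0.5, 0.75),
                                        names = FALSE) else rep(NA_real_, 3)
  list(records = records,
       summary = list(n_cases = nrow(cases),
                      n_detected_early = sum(early),
                      n_late = sum(late),
                      n_never = sum(is.na(cross)),
                      median_lead_hours = qs[2],
                      iqr_lead_hours = c(qs[1], qs[3])))
}
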