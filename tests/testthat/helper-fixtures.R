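# In-code fixtures: tiny event/encounter builders used across test files.

ts <- function(h, day = "2024-03-01") {
  as.POSIXct(day, tz = "UTC") + h * 3600
}

mk_encounter <- function(encounter_id = "E1", patient_id = "P1",
                         arrival = ts(0), discharge = ts(48),
                         encounter_type = "ed_to_hosp",
                         died_in_hospital = FALSE, ...) {
  data.frame(encounter_id = encounter_id, patient_id = patient_id,
             arrival_time = arrival, discharge_time = discharge,
             encounter_type = encounter_type,
             died_in_hospital = died_in_hospital, ...,
             stringsAsFactors = FALSE)
}

# mk_events("E1", list(c(1, "temperature_c", 39), c(2, "blood_culture_order")))
mk_events <- function(encounter_id, specs, patient_id = "P1") {
  rows <- lapply(specs, function(sp) {
    data.frame(encounter_id = encounter_id, patient_id = patient_id,
               time = if (inherits(sp[[1]], "POSIXt")) sp[[1]] else
                 ts(as.numeric(sp[[1]])),
               kind = "lab", concept = sp[[2]],
               value = if (length(sp) >= 3) as.numeric(sp[[3]]) else NA_real_,
               antibiotic_name = if (length(sp) >= 4) sp[[4]] else NA_character_,
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  ev[order(ev$encounter_id, ev$time), , drop = FALSE]
}

mk_predictions <- function(encounter_id, hours, scores) {
  data.frame(encounter_id = encounter_id, time = ts(hours),
             score = scores, stringsAsFactors = FALSE)
}

mk_labels <- function(encounter_id, definition = "SEPSIS3", is_case = TRUE,
                      time_zero_h = NA) {
  data.frame(encounter_id = encounter_id, definition = definition,
             is_case = is_case,
             time_zero = if (all(is.na(time_zero_h)))
               as.POSIXct(rep(NA_real_, length(encounter_id)),
                          origin = "1970-01-01", tz = "UTC") else ts(time_zero_h),
             stringsAsFactors = FALSE)
}

# Independent pairwise-concordance oracle for AUROC (ties count one half).
auroc_brute <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}
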