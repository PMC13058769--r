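#' Clinical concept vocabulary
#'
#' The event stream uses a fixed controlled vocabulary of concept codes.
#' Measurement concepts carry a numeric `value`; action concepts (orders,
#' drug administrations, device starts) carry none. Site-specific codes can
#' be admitted through the `extra` registry argument of [read_events()]; the
#' mapping of raw EHR codes onto this vocabulary is assumed to have happened
#' upstream.
#'
#' @return A data.frame with columns `concept`, `kind` (the event kind the
#'   concept belongs to) and `is_measurement`.
#' @export
concept_registry <- function() {
  measurements <- data.frame(
    concept = c("temperature_c", "heart_rate", "resp_rate", "sbp_mmHg",
                "map_mmHg", "wbc_k_per_uL", "band_pct", "lactate_mmol_L",
                "creatinine_mg_dL", "bilirubin_mg_dL", "platelets_k_per_uL",
                "inr", "pao2_fio2", "gcs"),
    kind = c(rep("vital", 5), rep("lab", 9)),
    is_measurement = TRUE,
    stringsAsFactors = FALSE
  )
  actions <- data.frame(
    concept = c("blood_culture_order", "lactate_order", "iv_antibiotic_admin",
                "vasopressor_admin", "mech_vent_start"),
    kind = c("order", "order", "med_admin", "med_admin", "procedure"),
    is_measurement = FALSE,
    stringsAsFactors = FALSE
  )
  rbind(measurements, actions)
}

measurement_concepts <- function() {
  reg <- concept_registry()
  reg$concept[reg$is_measurement]
}

#' Sepsis-related clinical action concepts
#'
#' The actions used for pre-treatment censoring of the prediction stream:
#' ordering of lactic acid, blood cultures, or intravenous antibiotics.
#'
#' @return Character vector of concept codes.
#' @export
sepsis_action_concepts <- function() {
  c("lactate_order", "blood_culture_order", "iv_antibiotic_admin")
}
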