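#' Simulation configuration for the synthetic EHR generator
#'
#' The generator emulates a silent-deployment evaluation cohort: a mix of
#' ED-only and admitted encounters, per-definition sepsis incidence, a
#' lognormal arrival-to-time-zero distribution per definition, and a
#' 15-minute score stream with controllable discrimination (binormal latent
#' model) and calibration. Case encounters receive constructively planted
#' event bundles that satisfy exactly one definition's criteria at known
#' times, so that phenotype recovery can be checked exactly.
#'
#' @param n_encounters Number of encounters to generate.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param study_start Start of the study window (POSIXct, UTC).
#' @param study_weeks Length of the study window in weeks; arrivals are
#'   uniform over the window.
#' @param encounter_type_mix Probability vector over the five encounter
#'   types; must sum to 1.
#' @param sepsis_incidence_by_definition Named probabilities for SEPSIS3,
#'   SEP1 and ASE. Case assignment is mutually exclusive across definitions
#'   and restricted to admitted encounter types.
#' @param arrival_to_t0_hours Per definition, `c(median, q1, q3)` in hours of
#'   the arrival-to-time-zero distribution; matched by a lognormal.
#' @param target_auroc Intended discrimination of the score against the
#'   any-definition case indicator, in (0.5, 1).
#' @param calibration_slope,calibration_intercept Logit-scale calibration map
#'   applied to all emitted scores; slope 1 / intercept 0 is the identity
#'   (perfectly calibrated peak scores by construction).
#' @param score_cadence_minutes Score cadence (default 15 minutes).
#' @param mortality_given_sepsis Named in-hospital mortality probabilities
#'   for cases of each definition.
#' @param mortality_no_sepsis Mortality probability for non-cases.
#' @param short_stay_fraction Fraction of encounters planted with a stay
#'   under 1 hour (exercises the inclusion filter).
#' @param multi_encounter_patient_fraction Fraction of patients carrying 2-3
#'   encounters (exercises the patient-clustered bootstrap).
#' @param ramp_lead_hours Nominal lead: case scores step up to the
#'   encounter's peak this long before time zero (plus half a cadence, so the
#'   median first-crossing lead equals the nominal value on the 15-minute
#'   grid).
#' @param ramp_shape `"step"` (default; exact lead-time semantics) or
#'   `"logistic"`.
#' @param ramp_logistic_scale_hours Time scale of the logistic ramp.
#' @param baseline_score_fraction Case pre-ramp scores sit at this fraction
#'   of the encounter peak.
#' @param action_order_fraction Fraction of non-case encounters receiving a
#'   lactate order (half as many receive blood cultures / IV antibiotics),
#'   to exercise pre-treatment censoring.
#' @param vitals_interval_hours Spacing of background vital-sign sets.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_encounters,
                       seed = 1L,
                       study_start = as.POSIXct("2024-01-01 00:00:00", tz = "UTC"),
                       study_weeks = 26,
                       encounter_type_mix = c(ed_only = 0.681, ed_to_hosp = 0.218,
                                              or_to_hosp = 0.049,
                                              direct_admission = 0.045,
                                              ob_to_hosp = 0.007),
                       sepsis_incidence_by_definition = c(SEPSIS3 = 0.029,
                                                          SEP1 = 0.012,
                                                          ASE = 0.020),
                       arrival_to_t0_hours = list(
                         SEPSIS3 = c(median = 4.1, q1 = 1.2, q3 = 25.2),
                         SEP1 = c(median = 5.8, q1 = 1.8, q3 = 31.3),
                         ASE = c(median = 1.7, q1 = 0.7, q3 = 11.6)),
                       target_auroc = 0.89,
                       calibration_slope = 1,
                       calibration_intercept = 0,
                       score_cadence_minutes = 15L,
                       mortality_given_sepsis = c(SEPSIS3 = 0.142, SEP1 = 0.219,
                                                  ASE = 0.187),
                       mortality_no_sepsis = 0.005,
                       short_stay_fraction = 8995 / 207489,
                       multi_encounter_patient_fraction = 0.10,
                       ramp_lead_hours = 4,
                       ramp_shape = c("step", "logistic"),
                       ramp_logistic_scale_hours = 0.25,
                       baseline_score_fraction = 0.12,
                       action_order_fraction = 0.15,
                       vitals_interval_hours = 4) {
  ramp_shape <- match.arg(ramp_shape)
  types <- c("ed_only", "ed_to_hosp", "or_to_hosp", "direct_admission",
             "ob_to_hosp")
  defs <- c("SEPSIS3", "SEP1", "ASE")
  if (n_encounters < 1) stop("config error: n_encounters must be >= 1")
  if (!all(types %in% names(encounter_type_mix))) {
    stop("config error: encounter_type_mix must name all five encounter types")
  }
  encounter_type_mix <- encounter_type_mix[types]
  if (abs(sum(encounter_type_mix) - 1) > 1e-6 || any(encounter_type_mix < 0)) {
    stop("config error: encounter_type_mix must be a probability vector summing to 1")
  }
  inc <- sepsis_incidence_by_definition
  if (!all(defs %in% names(inc)) || any(inc < 0) || any(inc > 1)) {
    stop("config error: sepsis_incidence_by_definition must give probabilities for SEPSIS3, SEP1, ASE")
  }
  admitted_p <- sum(encounter_type_mix[c("ed_to_hosp", "direct_admission",
                                         "or_to_hosp")])
  if (sum(inc) > admitted_p + 1e-12) {
    stop(sprintf(
      "config error: total sepsis incidence %.3f exceeds the admitted fraction %.3f (cases are planted in admitted encounters)",
      sum(inc), admitted_p))
  }
  if (target_auroc <= 0.5 || target_auroc >= 1) {
    stop("config error: target_auroc must lie in (0.5, 1)")
  }
  if (mortality_no_sepsis < 0 || mortality_no_sepsis > 1 ||
      any(mortality_given_sepsis < 0) || any(mortality_given_sepsis > 1)) {
    stop("config error: mortality parameters must be probabilities")
  }
  structure(list(
    n_encounters = as.integer(n_encounters), seed = as.integer(seed),
    study_start = as.POSIXct(study_start, tz = "UTC"),
    study_weeks = study_weeks,
    encounter_type_mix = encounter_type_mix,
    sepsis_incidence_by_definition = inc[defs],
    arrival_to_t0_hours = arrival_to_t0_hours,
    target_auroc = target_auroc,
    calibration_slope = calibration_slope,
    calibration_intercept = calibration_intercept,
    score_cadence_minutes = as.integer(score_cadence_minutes),
    mortality_given_sepsis = mortality_given_sepsis[defs],
    mortality_no_sepsis = mortality_no_sepsis,
    short_stay_fraction = short_stay_fraction,
    multi_encounter_patient_fraction = multi_encounter_patient_fraction,
    ramp_lead_hours = ramp_lead_hours, ramp_shape = ramp_shape,
    ramp_logistic_scale_hours = ramp_logistic_scale_hours,
    baseline_score_fraction = baseline_score_fraction,
    action_order_fraction = action_order_fraction,
    vitals_interval_hours = vitals_interval_hours), class = "sim_config")
}

pclamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Lognormal matched to a printed median and IQR:
# meanlog = log(median), sdlog = log(q3/q1) / (2 * qnorm(0.75)).
lnorm_from_median_iqr <- function(spec) {
  c(meanlog = log(spec[["median"]]),
    sdlog = log(spec[["q3"]] / spec[["q1"]]) / (2 * stats::qnorm(0.75)))
}

# Binormal latent separation achieving the target AUROC with unit variances.
binormal_mu <- function(auroc) sqrt(2) * stats::qnorm(auroc)

# Peak risk score: 100 * P(case | z) under the binormal mixture with
# prevalence pi -- perfectly calibrated by construction.
calibrated_peak <- function(z, mu, pi_total) {
  pi_eff <- max(pi_total, 1e-6)
  100 * stats::plogis(stats::qlogis(pi_eff) + mu * z - mu^2 / 2)
}

apply_calibration_map <- function(score, slope, intercept) {
  if (slope == 1 && intercept == 0) return(score)
  p <- pclamp(score / 100, 1e-9, 1 - 1e-9)
  100 * stats::plogis(intercept + slope * stats::qlogis(p))
}

# Internal: encounter frame with hidden case assignment columns.
# RNG state must already be seeded by the caller.
.simulate_encounters <- function(config) {
  n <- config$n_encounters
  defs <- c("SEPSIS3", "SEP1", "ASE")

  # Patient clustering: a fraction of patients carry 2-3 encounters.
  f <- config$multi_encounter_patient_fraction
  k <- sample(1:3, n, replace = TRUE, prob = c(1 - f, f / 2, f / 2))
  cum <- cumsum(k)
  npat <- which(cum >= n)[1]
  k <- k[seq_len(npat)]
  k[npat] <- k[npat] - (cum[npat] - n)
  patient_id <- rep(sprintf("P%06d", seq_len(npat)), k)

  type <- sample(names(config$encounter_type_mix), n, replace = TRUE,
                 prob = config$encounter_type_mix)
  hospital_type <- sample(c("academic", "community", "critical_access"), n,
                          replace = TRUE, prob = c(0.43, 0.51, 0.06))
  age_years <- round(pclamp(stats::rnorm(n, 55, 20), 18, 100))
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.548, 0.452))
  race <- sample(c("asian", "black", "white", "other", "unknown"), n,
                 replace = TRUE, prob = c(0.035, 0.119, 0.696, 0.011, 0.139))
  ethnicity <- sample(c("hispanic", "non_hispanic", "unknown"), n,
                      replace = TRUE, prob = c(0.160, 0.805, 0.035))
  is_ed <- type %in% c("ed_only", "ed_to_hosp")
  esi <- rep(NA_integer_, n)
  esi[is_ed] <- sample(1:5, sum(is_ed), replace = TRUE,
                       prob = c(0.007, 0.300, 0.540, 0.145, 0.008))

  arrival_time <- round_minute(config$study_start +
                                 stats::runif(n, 0, config$study_weeks * 604800))

  # Exclusive case assignment among admitted encounter types.
  admitted <- type %in% c("ed_to_hosp", "direct_admission", "or_to_hosp")
  p_adm <- sum(config$encounter_type_mix[c("ed_to_hosp", "direct_admission",
                                           "or_to_hosp")])
  q <- config$sepsis_incidence_by_definition / p_adm
  u <- stats::runif(n)
  case_def <- rep(NA_character_, n)
  lo <- 0
  for (d in defs) {
    hit <- admitted & u >= lo & u < lo + q[[d]]
    case_def[hit] <- d
    lo <- lo + q[[d]]
  }
  is_case <- !is.na(case_def)

  # Arrival-to-time-zero offsets (hours), lognormal per definition.
  t0_offset_h <- rep(NA_real_, n)
  for (d in defs) {
    idx <- which(case_def == d)
    if (length(idx) == 0) next
    par <- lnorm_from_median_iqr(config$arrival_to_t0_hours[[d]])
    t0_offset_h[idx] <- pclamp(stats::rlnorm(length(idx), par[["meanlog"]],
                                             par[["sdlog"]]), 0.5, 21 * 24)
  }

  # Stays. Case stays extend past time zero far enough to hold each
  # definition's planted bundle (and to keep deaths clear of the ASE
  # antibiotic-day death exception for non-ASE cases).
  stay_h <- numeric(n)
  nc_ed <- !is_case & type == "ed_only"
  nc_other <- !is_case & type != "ed_only"
  stay_h[nc_ed] <- pclamp(stats::rlnorm(sum(nc_ed), log(4), 0.5), 1.1, 24)
  stay_h[nc_other] <- pclamp(stats::rlnorm(sum(nc_other), log(60), 0.6), 6, 720)
  if (any(is_case)) {
    post <- stats::rlnorm(sum(is_case), log(72), 0.5)
    min_post <- c(SEPSIS3 = 63, SEP1 = 2, ASE = 80)[case_def[is_case]]
    stay_h[is_case] <- t0_offset_h[is_case] + pmax(post, min_post)
  }

  # Planted sub-hour stays (inclusion-filter fodder) among ED-only non-cases.
  n_short <- round(config$short_stay_fraction * n)
  cand <- which(nc_ed)
  if (n_short > 0 && length(cand) > 0) {
    short_idx <- if (length(cand) <= n_short) cand else
      sample(cand, n_short)
    stay_h[short_idx] <- stats::runif(length(short_idx), 5 / 60, 55 / 60)
  }

  u2 <- stats::runif(n)
  died <- ifelse(is_case,
                 u2 < config$mortality_given_sepsis[
                   ifelse(is_case, case_def, "SEPSIS3")],
                 u2 < config$mortality_no_sepsis)

  discharge_time <- round_minute(arrival_time + stay_h * 3600)
  t0_time <- as.POSIXct(rep(NA_real_, n), origin = "1970-01-01", tz = "UTC")
  t0_time[is_case] <- round_minute(arrival_time[is_case] +
                                     t0_offset_h[is_case] * 3600)

  data.frame(
    encounter_id = sprintf("E%06d", seq_len(n)),
    patient_id = patient_id,
    arrival_time = arrival_time, discharge_time = discharge_time,
    encounter_type = type, hospital_type = hospital_type,
    age_years = age_years, sex = sex, race = race, ethnicity = ethnicity,
    esi = esi, died_in_hospital = died,
    case_def = case_def, t0_time = t0_time,
    stringsAsFactors = FALSE)
}

.public_encounter_cols <- c("encounter_id", "patient_id", "arrival_time",
                            "discharge_time", "encounter_type",
                            "hospital_type", "age_years", "sex", "race",
                            "ethnicity", "esi", "died_in_hospital")

#' Generate encounter metadata only
#'
#' Fast path that draws the encounter table (types, stays, demographics,
#' planted short stays) without materializing event or score streams. The
#' encounter table is identical to the one produced by [generate_cohort()]
#' under the same config.
#'
#' @param config A [sim_config()].
#' @return A data.frame of encounters.
#' @export
generate_encounters <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sim <- .simulate_encounters(config)
  sim[, .public_encounter_cols]
}

.concept_kind <- function(concepts) {
  reg <- concept_registry()
  reg$kind[match(concepts, reg$concept)]
}

.event_frame <- function(enc_idx, sim, time, concept, value = NA_real_,
                         antibiotic_name = NA_character_) {
  data.frame(encounter_id = sim$encounter_id[enc_idx],
             patient_id = sim$patient_id[enc_idx],
             time = time, kind = .concept_kind(concept), concept = concept,
             value = value, antibiotic_name = antibiotic_name,
             stringsAsFactors = FALSE)
}

# Background vitals/labs are clamped so that no SIRS, SOFA, SEP-1 or ASE
# criterion can fire from them: temperatures stay in (36.0, 38.3], heart
# rates <= 90, respiratory rates <= 20, blood pressures well above
# hypotension thresholds with within-encounter drift under 20 mmHg, and labs
# inside normal ranges with within-encounter ratios below any doubling or
# halving rule.
.background_events <- function(sim, config) {
  n <- nrow(sim)
  stay_h <- hours_between(sim$arrival_time, sim$discharge_time)
  n_sets <- pmax(1L, floor(stay_h / config$vitals_interval_hours) + 1L)
  enc_idx <- rep(seq_len(n), n_sets)
  set_k <- sequence(n_sets) - 1
  times <- round_minute(sim$arrival_time[enc_idx] +
                          set_k * config$vitals_interval_hours * 3600)
  m <- length(enc_idx)

  temp_b <- pclamp(stats::rnorm(n, 37.0, 0.15), 36.4, 37.9)
  hr_b <- pclamp(stats::rnorm(n, 76, 6), 58, 86)
  rr_b <- pclamp(stats::rnorm(n, 16, 1.5), 12, 19)
  sbp_b <- pclamp(stats::rnorm(n, 124, 8), 105, 145)
  map_b <- pclamp(stats::rnorm(n, 85, 5), 72, 97)

  vit <- rbind(
    .event_frame(enc_idx, sim, times, "temperature_c",
                 pclamp(temp_b[enc_idx] + stats::rnorm(m, 0, 0.12), 36.1, 38.25)),
    .event_frame(enc_idx, sim, times, "heart_rate",
                 pclamp(hr_b[enc_idx] + stats::rnorm(m, 0, 3), 50, 89)),
    .event_frame(enc_idx, sim, times, "resp_rate",
                 pclamp(rr_b[enc_idx] + stats::rnorm(m, 0, 0.8), 10, 20)),
    .event_frame(enc_idx, sim, times, "sbp_mmHg",
                 pclamp(sbp_b[enc_idx] + stats::rnorm(m, 0, 4),
                        pmax(95, sbp_b[enc_idx] - 9), sbp_b[enc_idx] + 9)),
    .event_frame(enc_idx, sim, times, "map_mmHg",
                 pclamp(map_b[enc_idx] + stats::rnorm(m, 0, 3), 70, 108)))

  # Admission labs (single draw per encounter, forced for Sepsis-3 cases so
  # a platelet baseline always exists).
  has_lab <- stats::runif(n) < 0.7
  has_lab[!is.na(sim$case_def) & sim$case_def == "SEPSIS3"] <- TRUE
  li <- which(has_lab)
  lab_t <- round_minute(sim$arrival_time[li] + 600)
  labs <- rbind(
    .event_frame(li, sim, lab_t, "wbc_k_per_uL",
                 pclamp(stats::rnorm(length(li), 8.2, 1.5), 4.6, 11.6)),
    .event_frame(li, sim, lab_t, "creatinine_mg_dL",
                 pclamp(stats::rnorm(length(li), 0.9, 0.12), 0.62, 1.18)),
    .event_frame(li, sim, lab_t, "platelets_k_per_uL",
                 pclamp(stats::rnorm(length(li), 250, 35), 165, 380)))
  rbind(vit, labs)
}

# Planted case bundles. Each bundle satisfies exactly one definition:
#  SEPSIS3: blood culture at t0, IV antibiotic 1 h later (suspicion = t0),
#           platelet fall to 40 at t0+2h (SOFA coagulation 3 vs baseline 0).
#           Antibiotics stop after one day and stays run >= 63 h past t0, so
#           the ASE antibiotic-day rule can never qualify, and no SIRS pair
#           exists for SEP-1.
#  SEP1:    two SIRS criteria (temp 39.2, HR 122) inside the concurrency
#           window, completed by lactate 2.5 at t0. No culture/antibiotics,
#           so Sepsis-3 and ASE cannot fire.
#  ASE:     blood culture and lactate 2.2 straddling t0 (order randomized),
#           first antibiotic 4 h after culture, repeated daily for 4 calendar
#           days. The planted lactate is not a SOFA component and background
#           SOFA stays 0, so Sepsis-3 cannot fire; no SIRS pair for SEP-1.
.planted_events <- function(sim, config) {
  out <- list()
  t0 <- sim$t0_time
  hrs <- function(h) h * 3600

  s3 <- which(sim$case_def == "SEPSIS3")
  if (length(s3) > 0) {
    out$s3 <- rbind(
      .event_frame(s3, sim, t0[s3], "blood_culture_order"),
      .event_frame(s3, sim, round_minute(t0[s3] + hrs(0.5)), "lactate_order"),
      .event_frame(s3, sim, round_minute(t0[s3] + hrs(1)), "iv_antibiotic_admin",
                   antibiotic_name = "piperacillin-tazobactam"),
      .event_frame(s3, sim, round_minute(t0[s3] + hrs(2)), "platelets_k_per_uL",
                   value = 40))
  }

  s1 <- which(sim$case_def == "SEP1")
  if (length(s1) > 0) {
    off <- hours_between(sim$arrival_time[s1], t0[s1])
    t_sirs1 <- round_minute(t0[s1] - hrs(pmin(2, 0.66 * off)))
    t_sirs2 <- round_minute(t0[s1] - hrs(pmin(1, 0.33 * off)))
    out$s1 <- rbind(
      .event_frame(s1, sim, t_sirs1, "temperature_c", value = 39.2),
      .event_frame(s1, sim, t_sirs2, "heart_rate", value = 122),
      .event_frame(s1, sim, t0[s1], "lactate_mmol_L", value = 2.5))
    attr(out$s1, "sirs_times") <- data.frame(
      encounter_id = sim$encounter_id[s1], sirs1_time = t_sirs1,
      sirs2_time = t_sirs2, stringsAsFactors = FALSE)
  }

  ase <- which(sim$case_def == "ASE")
  if (length(ase) > 0) {
    culture_first <- stats::runif(length(ase)) < 2 / 3
    c_t <- round_minute(ifelse(culture_first, as.numeric(t0[ase]),
                               as.numeric(t0[ase]) + hrs(1)))
    o_t <- round_minute(ifelse(culture_first, as.numeric(t0[ase]) + hrs(1),
                               as.numeric(t0[ase])))
    q_t <- round_minute(c_t + hrs(4))
    abx <- do.call(rbind, lapply(0:3, function(d) {
      .event_frame(ase, sim, round_minute(q_t + hrs(24 * d)),
                   "iv_antibiotic_admin", antibiotic_name = "ceftriaxone")
    }))
    out$ase <- rbind(
      .event_frame(ase, sim, c_t, "blood_culture_order"),
      .event_frame(ase, sim, round_minute(o_t + hrs(0.25)), "lactate_order"),
      .event_frame(ase, sim, o_t, "lactate_mmol_L", value = 2.2),
      abx)
    attr(out$ase, "components") <- data.frame(
      encounter_id = sim$encounter_id[ase], culture_time = c_t,
      od_time = o_t, qad_start = q_t, stringsAsFactors = FALSE)
  }

  # Sepsis-related actions in a slice of non-case encounters (censoring
  # fodder; none of these can complete any definition because non-case
  # streams carry no qualifying abnormality).
  nc <- which(is.na(sim$case_def))
  stay_h <- hours_between(sim$arrival_time, sim$discharge_time)
  u <- stats::runif(length(nc))
  frac <- config$action_order_fraction
  pick <- function(p_lo, p_hi) nc[u >= p_lo & u < p_hi]
  lac <- pick(0, frac)
  cul <- pick(frac * 0.2, frac * 0.2 + frac * 0.55)
  abx_nc <- pick(frac * 0.4, frac * 0.4 + frac * 0.27)
  rand_t <- function(idx) {
    round_minute(sim$arrival_time[idx] +
                   stats::runif(length(idx), 0.05, 0.95) * stay_h[idx] * 3600)
  }
  if (length(lac) > 0) out$nc_lac <- .event_frame(lac, sim, rand_t(lac), "lactate_order")
  if (length(cul) > 0) out$nc_cul <- .event_frame(cul, sim, rand_t(cul), "blood_culture_order")
  if (length(abx_nc) > 0) {
    out$nc_abx <- .event_frame(abx_nc, sim, rand_t(abx_nc),
                               "iv_antibiotic_admin", antibiotic_name = "cefazolin")
  }
  out
}

.planted_truth <- function(sim, planted) {
  defs <- c("SEPSIS3", "SEP1", "ASE")
  na_t <- as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC")
  rows <- lapply(defs, function(d) {
    is_case <- !is.na(sim$case_def) & sim$case_def == d
    tr <- data.frame(encounter_id = sim$encounter_id, definition = d,
                     is_case = is_case, time_zero = na_t,
                     culture_time = na_t, antibiotic_time = na_t,
                     qad_start = na_t, od_time = na_t,
                     sirs1_time = na_t, sirs2_time = na_t,
                     stringsAsFactors = FALSE)
    tr$time_zero[is_case] <- sim$t0_time[is_case]
    if (d == "SEPSIS3" && any(is_case)) {
      tr$culture_time[is_case] <- sim$t0_time[is_case]
      tr$antibiotic_time[is_case] <- round_minute(sim$t0_time[is_case] + 3600)
      tr$od_time[is_case] <- round_minute(sim$t0_time[is_case] + 7200)
    }
    if (d == "SEP1" && !is.null(planted$s1)) {
      st <- attr(planted$s1, "sirs_times")
      i <- match(st$encounter_id, tr$encounter_id)
      tr$sirs1_time[i] <- st$sirs1_time
      tr$sirs2_time[i] <- st$sirs2_time
      tr$od_time[i] <- sim$t0_time[i]
    }
    if (d == "ASE" && !is.null(planted$ase)) {
      comp <- attr(planted$ase, "components")
      i <- match(comp$encounter_id, tr$encounter_id)
      tr$culture_time[i] <- comp$culture_time
      tr$od_time[i] <- comp$od_time
      tr$qad_start[i] <- comp$qad_start
      tr$antibiotic_time[i] <- comp$qad_start
      tr$time_zero[i] <- round_minute(pmin(comp$culture_time, comp$od_time))
    }
    tr
  })
  out <- do.call(rbind, rows)
  out[order(out$encounter_id, out$definition), , drop = FALSE]
}

.unit_intervals <- function(sim) {
  n <- nrow(sim)
  is_case <- !is.na(sim$case_def)
  ed <- sim$encounter_type %in% c("ed_only", "ed_to_hosp")
  stay_h <- hours_between(sim$arrival_time, sim$discharge_time)

  ed_end <- sim$discharge_time
  adm_from_ed <- sim$encounter_type == "ed_to_hosp"
  ed_end[adm_from_ed] <- round_minute(sim$arrival_time[adm_from_ed] +
                                        pmin(6, 0.3 * stay_h[adm_from_ed]) * 3600)
  seg <- function(ids, unit, start, end) {
    if (length(ids) == 0) return(NULL)
    data.frame(encounter_id = ids, unit = unit, start = start, end = end,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  # ED segments
  i <- which(ed)
  rows$ed <- seg(sim$encounter_id[i], "ED", sim$arrival_time[i], ed_end[i])
  # Post-ED / non-ED segments
  i <- which(!(sim$encounter_type == "ed_only"))
  ward_start <- ifelse(sim$encounter_type[i] == "ed_to_hosp",
                       as.numeric(ed_end[i]), as.numeric(sim$arrival_time[i]))
  ward_start <- as.POSIXct(ward_start, origin = "1970-01-01", tz = "UTC")
  icu_start <- as.POSIXct(pmax(as.numeric(ward_start),
                               as.numeric(sim$t0_time[i])),
                          origin = "1970-01-01", tz = "UTC")
  case_i <- is_case[i]
  ward_end <- sim$discharge_time[i]
  ward_end[case_i] <- icu_start[case_i]
  keep_ward <- which(as.numeric(ward_end) > as.numeric(ward_start))
  rows$ward <- seg(sim$encounter_id[i][keep_ward], "ward",
                   ward_start[keep_ward], ward_end[keep_ward])
  ci <- which(case_i)
  rows$icu <- seg(sim$encounter_id[i][ci], "ICU", icu_start[ci],
                  sim$discharge_time[i][ci])
  out <- do.call(rbind, rows)
  out <- out[as.numeric(out$end) > as.numeric(out$start), , drop = FALSE]
  out <- out[order(out$encounter_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.score_stream <- function(sim, config) {
  n <- nrow(sim)
  is_case <- !is.na(sim$case_def)
  mu <- binormal_mu(config$target_auroc)
  pi_total <- sum(config$sepsis_incidence_by_definition)
  z <- stats::rnorm(n) + mu * is_case
  peak <- calibrated_peak(z, mu, pi_total)

  cadence <- config$score_cadence_minutes
  stay_min <- round(as.numeric(sim$discharge_time) -
                      as.numeric(sim$arrival_time)) / 60
  n_pred <- pmax(1L, as.integer(stay_min %/% cadence) + 1L)
  enc_idx <- rep(seq_len(n), n_pred)
  kk <- sequence(n_pred) - 1
  time_num <- as.numeric(sim$arrival_time)[enc_idx] + kk * cadence * 60

  u <- stats::runif(length(enc_idx))
  jit <- 0.55 + 0.45 * u
  r0 <- config$baseline_score_fraction
  score <- peak[enc_idx] * jit
  if (any(is_case)) {
    # Case streams: baseline fraction of peak, then a ramp to the peak
    # starting (lead + cadence/2) before time zero.
    s_start <- as.numeric(sim$t0_time) -
      (config$ramp_lead_hours * 3600 + cadence * 60 / 2)
    ci <- is_case[enc_idx]
    if (config$ramp_shape == "step") {
      on_ramp <- ci & time_num >= s_start[enc_idx]
      score[ci] <- peak[enc_idx][ci] * r0 * jit[ci]
      score[on_ramp] <- peak[enc_idx][on_ramp]
    } else {
      tau <- config$ramp_logistic_scale_hours * 3600
      frac <- stats::plogis((time_num - s_start[enc_idx]) / tau)
      score[ci] <- peak[enc_idx][ci] * pmax(r0 * jit[ci], frac[ci])
    }
  }
  # Non-case encounters: place the peak at one random in-stay prediction so
  # the encounter maximum equals the calibrated peak exactly.
  last_is_discharge <- (stay_min %% cadence) == 0 & n_pred > 1
  elig_n <- pmax(1L, n_pred - as.integer(last_is_discharge))
  j <- 1L + as.integer(floor(stats::runif(n) * elig_n))
  offsets <- c(0L, cumsum(n_pred))[seq_len(n)]
  peak_pos <- offsets + pmin(j, elig_n)
  nc_pos <- peak_pos[!is_case]
  score[nc_pos] <- peak[!is_case]

  score <- apply_calibration_map(score, config$calibration_slope,
                                 config$calibration_intercept)
  data.frame(encounter_id = sim$encounter_id[enc_idx],
             time = as.POSIXct(time_num, origin = "1970-01-01", tz = "UTC"),
             score = pclamp(score, 0, 100), stringsAsFactors = FALSE)
}

#' Generate a full synthetic evaluation cohort
#'
#' Draws encounters, a clinical event stream with constructively planted
#' sepsis cases, a score stream at the configured cadence, and the planted
#' truth table. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with `encounters`, `unit_intervals`, `events`,
#'   `predictions`, `truth`, and the `config` used.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sim <- .simulate_encounters(config)

  background <- .background_events(sim, config)
  planted <- .planted_events(sim, config)
  events <- rbind(background,
                  do.call(rbind, unname(lapply(planted, function(x) {
                    attributes(x)[c("sirs_times", "components")] <- NULL
                    x
                  }))))
  # Events must fall inside the stay.
  keep <- events$time >= sim$arrival_time[match(events$encounter_id,
                                                sim$encounter_id)] &
    events$time <= sim$discharge_time[match(events$encounter_id,
                                            sim$encounter_id)]
  events <- events[keep, , drop = FALSE]
  events <- events[order(events$encounter_id, events$time), , drop = FALSE]
  rownames(events) <- NULL

  predictions <- .score_stream(sim, config)
  truth <- .planted_truth(sim, planted)
  units <- .unit_intervals(sim)

  list(encounters = sim[, .public_encounter_cols],
       unit_intervals = units, events = events, predictions = predictions,
       truth = truth, config = config)
}

#' Plant a score stream for a single encounter
#'
#' Standalone single-encounter version of the score model used by
#' [generate_cohort()]: a latent binormal draw sets the encounter's
#' calibrated peak score; case streams ramp up to the peak ahead of time
#' zero, non-case streams jitter below the peak, which is placed at a random
#' prediction time.
#'
#' @param arrival_time,discharge_time Encounter bounds (POSIXct).
#' @param is_case Logical.
#' @param time_zero Time zero (POSIXct) if `is_case`.
#' @param config A [sim_config()].
#' @return A data.frame of predictions (`time`, `score`).
#' @export
plant_score_stream <- function(arrival_time, discharge_time, is_case,
                               time_zero = NULL, config) {
  stopifnot(inherits(config, "sim_config"))
  if (is_case && (is.null(time_zero) || time_zero < arrival_time ||
                  time_zero > discharge_time)) {
    stop("is_case implies time_zero within the encounter", call. = FALSE)
  }
  sim <- data.frame(
    encounter_id = "E000001", patient_id = "P000001",
    arrival_time = as.POSIXct(arrival_time, tz = "UTC"),
    discharge_time = as.POSIXct(discharge_time, tz = "UTC"),
    case_def = if (is_case) "SEPSIS3" else NA_character_,
    t0_time = if (is_case) as.POSIXct(time_zero, tz = "UTC") else
      as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC"),
    stringsAsFactors = FALSE)
  .score_stream(sim, config)[, c("time", "score")]
}
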