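#' Criteria configuration for the computable sepsis definitions
#'
#' Every threshold and window of the three definitions is exposed here so a
#' site can override any number. Defaults follow the primary published
#' definitions: Sepsis-3 (suspected infection by culture-antibiotic pairing
#' plus an acute SOFA rise of 2 or more), the SEP-1 severe-sepsis logic
#' (two or more SIRS criteria concurrent with organ dysfunction), and the
#' CDC Adult Sepsis Event (blood culture, four qualifying antibiotic days,
#' and concurrent organ dysfunction).
#'
#' Boundary conventions: SIRS and SEP-1 thresholds are strict (`>` / `<`);
#' the ASE lactate threshold is inclusive (`>=` 2.0), per the respective
#' definition texts.
#'
#' @param abx_after_culture_hours Antibiotic up to this long after a culture
#'   forms a suspected-infection pair (default 72 h).
#' @param culture_after_abx_hours Culture up to this long after an
#'   antibiotic forms a pair (default 24 h).
#' @param sofa_window_before_hours,sofa_window_after_hours SOFA-change
#'   window around the suspicion time (default -48 h, +24 h).
#' @param sofa_lookback_hours Lookback for the worst value entering each
#'   SOFA subscore (default 24 h).
#' @param sofa_delta Required acute SOFA rise (default 2).
#' @param sirs_window_hours Rolling concurrency window for SIRS criteria
#'   (default 6 h).
#' @param sep1_window_hours Rolling concurrency window tying SIRS and
#'   SEP-1 organ dysfunction together (default 6 h).
#' @param ase_culture_window_days ASE organ-dysfunction window around the
#'   blood culture, in calendar days (default 2).
#' @param qad_min_days Minimum qualifying antibiotic days (default 4).
#' @param qad_max_gap_days Largest bridged gap in the antibiotic-day run
#'   (default 1 day).
#' @param ase_time_zero `"component_min"` (default): time zero is the
#'   earliest of culture, antibiotic-day start and organ dysfunction;
#'   `"culture"`: time zero is the culture time.
#' @param youden_style Retained here for completeness of the reporting
#'   conventions; see [youden_top_left()].
#' @param pre_arrival_lookback_hours Events up to this long before arrival
#'   participate in criteria (default 0: on-arrival onward only).
#' @param thresholds Named list of numeric thresholds; any subset may be
#'   overridden. See the default value for the full set.
#' @return A list of class `criteria_config`.
#' @export
criteria_config <- function(abx_after_culture_hours = 72,
                            culture_after_abx_hours = 24,
                            sofa_window_before_hours = 48,
                            sofa_window_after_hours = 24,
                            sofa_lookback_hours = 24,
                            sofa_delta = 2,
                            sirs_window_hours = 6,
                            sep1_window_hours = 6,
                            ase_culture_window_days = 2,
                            qad_min_days = 4,
                            qad_max_gap_days = 1,
                            ase_time_zero = c("component_min", "culture"),
                            youden_style = c("top_left", "youden_j"),
                            pre_arrival_lookback_hours = 0,
                            thresholds = list()) {
  defaults <- list(
    sirs_temp_high = 38.3, sirs_temp_low = 36.0, sirs_hr = 90, sirs_rr = 20,
    sirs_wbc_high = 12, sirs_wbc_low = 4, sirs_band_pct = 10,
    sep1_sbp = 90, sep1_map = 65, sep1_sbp_drop = 40, sep1_lactate = 2.0,
    sep1_creatinine = 2.0, sep1_bilirubin = 2.0, sep1_platelets = 100,
    sep1_inr = 1.5,
    ase_lactate = 2.0, ase_creatinine_ratio = 2, ase_bilirubin = 2.0,
    ase_bilirubin_ratio = 2, ase_platelets = 100, ase_platelet_decline = 0.5)
  unknown <- setdiff(names(thresholds), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown threshold(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  defaults[names(thresholds)] <- thresholds
  stopifnot(sirs_window_hours > 0, sep1_window_hours > 0,
            ase_culture_window_days > 0, qad_min_days >= 1)
  structure(list(
    abx_after_culture_hours = abx_after_culture_hours,
    culture_after_abx_hours = culture_after_abx_hours,
    sofa_window_before_hours = sofa_window_before_hours,
    sofa_window_after_hours = sofa_window_after_hours,
    sofa_lookback_hours = sofa_lookback_hours,
    sofa_delta = sofa_delta,
    sirs_window_hours = sirs_window_hours,
    sep1_window_hours = sep1_window_hours,
    ase_culture_window_days = ase_culture_window_days,
    qad_min_days = qad_min_days, qad_max_gap_days = qad_max_gap_days,
    ase_time_zero = match.arg(ase_time_zero),
    youden_style = match.arg(youden_style),
    pre_arrival_lookback_hours = pre_arrival_lookback_hours,
    thresholds = defaults), class = "criteria_config")
}

.vals_in <- function(events, concept, from, to) {
  # values of `concept` with time in (from, to]
  sel <- events$concept == concept & events$time > from & events$time <= to
  events$value[sel]
}

.times_of <- function(events, concept) {
  events$time[events$concept == concept]
}

#' Count SIRS criteria satisfied in a rolling window
#'
#' Counts how many of the four SIRS criteria (temperature > 38.3 or
#' < 36.0 degrees C; heart rate > 90; respiratory rate > 20; WBC > 12 or
#' < 4 k/uL or bands > 10%) are each satisfied by at least one measurement
#' in `(at_time - window, at_time]`.
#'
#' @param events Events of a single encounter, sorted by time.
#' @param at_time Evaluation time (POSIXct).
#' @param window_hours Rolling window length in hours.
#' @param config A [criteria_config()].
#' @return Integer 0-4.
#' @export
sirs_count <- function(events, at_time, window_hours = 6,
                       config = criteria_config()) {
  th <- config$thresholds
  from <- at_time - window_hours * 3600
  temp <- .vals_in(events, "temperature_c", from, at_time)
  hr <- .vals_in(events, "heart_rate", from, at_time)
  rr <- .vals_in(events, "resp_rate", from, at_time)
  wbc <- .vals_in(events, "wbc_k_per_uL", from, at_time)
  bands <- .vals_in(events, "band_pct", from, at_time)
  sum(any(temp > th$sirs_temp_high) || any(temp < th$sirs_temp_low),
      any(hr > th$sirs_hr),
      any(rr > th$sirs_rr),
      any(wbc > th$sirs_wbc_high) || any(wbc < th$sirs_wbc_low) ||
        any(bands > th$sirs_band_pct))
}

.sofa_sub <- function(worst, breaks, scores) {
  # worst: scalar or NA; breaks define half-open score bands
  if (is.na(worst)) return(0L)
  scores[findInterval(worst, breaks) + 1L]
}

#' SOFA score from the worst values in a lookback window
#'
#' Standard six-organ SOFA; each subscore is taken from the worst qualifying
#' value in `(at_time - lookback, at_time]`, and unmeasured components score
#' 0. Cardiovascular scores 1 for MAP < 70 mmHg and 3 for any vasopressor
#' administration in the window (dose information is not modeled).
#'
#' @param events Events of a single encounter, sorted by time.
#' @param at_time Evaluation time (POSIXct).
#' @param config A [criteria_config()] (uses `sofa_lookback_hours`).
#' @return A list with `total` (0-24) and `subscores` (named integer vector).
#' @export
sofa_score <- function(events, at_time, config = criteria_config()) {
  from <- at_time - config$sofa_lookback_hours * 3600
  worst_min <- function(concept) {
    v <- .vals_in(events, concept, from, at_time)
    if (length(v) == 0) NA_real_ else min(v)
  }
  worst_max <- function(concept) {
    v <- .vals_in(events, concept, from, at_time)
    if (length(v) == 0) NA_real_ else max(v)
  }
  pf <- worst_min("pao2_fio2")
  resp <- if (is.na(pf)) 0L else (pf < 400) + (pf < 300) + (pf < 200) + (pf < 100)
  plt <- worst_min("platelets_k_per_uL")
  coag <- if (is.na(plt)) 0L else (plt < 150) + (plt < 100) + (plt < 50) + (plt < 20)
  bili <- worst_max("bilirubin_mg_dL")
  liver <- if (is.na(bili)) 0L else
    (bili >= 1.2) + (bili >= 2.0) + (bili >= 6.0) + (bili >= 12.0)
  vaso <- length(.times_of(events, "vasopressor_admin")) > 0 &&
    any(.times_of(events, "vasopressor_admin") > from &
          .times_of(events, "vasopressor_admin") <= at_time)
  map <- worst_min("map_mmHg")
  cardio <- if (vaso) 3L else if (!is.na(map) && map < 70) 1L else 0L
  gcs <- worst_min("gcs")
  cns <- if (is.na(gcs)) 0L else
    (gcs < 15) + (gcs < 13) + (gcs < 10) + (gcs < 6)
  cr <- worst_max("creatinine_mg_dL")
  renal <- if (is.na(cr)) 0L else
    (cr >= 1.2) + (cr >= 2.0) + (cr >= 3.5) + (cr >= 5.0)
  sub <- c(respiration = as.integer(resp), coagulation = as.integer(coag),
           liver = as.integer(liver), cardiovascular = as.integer(cardio),
           cns = as.integer(cns), renal = as.integer(renal))
  list(total = sum(sub), subscores = sub)
}

#' Detect suspected-infection episodes
#'
#' Pairs of blood culture and IV antibiotic where the antibiotic starts
#' within 72 h after the culture, or the culture is drawn within 24 h after
#' the antibiotic. The suspicion time is the earlier of the pair.
#'
#' @param events Events of a single encounter, sorted by time.
#' @param config A [criteria_config()].
#' @return A data.frame `(suspicion_time, culture_time, antibiotic_time)`
#'   sorted by suspicion time (0 rows when none).
#' @export
detect_suspected_infection <- function(events, config = criteria_config()) {
  cultures <- .times_of(events, "blood_culture_order")
  abx <- .times_of(events, "iv_antibiotic_admin")
  empty <- data.frame(suspicion_time = as.POSIXct(character(), tz = "UTC"),
                      culture_time = as.POSIXct(character(), tz = "UTC"),
                      antibiotic_time = as.POSIXct(character(), tz = "UTC"))
  if (length(cultures) == 0 || length(abx) == 0) return(empty)
  grid <- expand.grid(culture_time = cultures, antibiotic_time = abx)
  d_h <- hours_between(grid$culture_time, grid$antibiotic_time)
  ok <- (d_h >= 0 & d_h <= config$abx_after_culture_hours) |
    (d_h <= 0 & -d_h <= config$culture_after_abx_hours)
  grid <- grid[ok, , drop = FALSE]
  if (nrow(grid) == 0) return(empty)
  grid$suspicion_time <- pmin(grid$culture_time, grid$antibiotic_time)
  grid <- grid[order(grid$suspicion_time, grid$culture_time,
                     grid$antibiotic_time), , drop = FALSE]
  rownames(grid) <- NULL
  grid[, c("suspicion_time", "culture_time", "antibiotic_time")]
}

.na_time <- function() as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC")

.label <- function(encounter_id, definition, is_case = FALSE,
                   time_zero = .na_time(), components = list()) {
  list(encounter_id = encounter_id, definition = definition,
       is_case = is_case, time_zero = time_zero, components = components)
}

.filter_encounter_events <- function(events, encounter, config) {
  lo <- encounter$arrival_time - config$pre_arrival_lookback_hours * 3600
  events[events$time >= lo & events$time <= encounter$discharge_time, ,
         drop = FALSE]
}

#' Sepsis-3 label for one encounter
#'
#' Case if and only if some suspected-infection pair shows an acute SOFA
#' rise of at least `sofa_delta` within the configured window around the
#' suspicion time (window maximum minus the pre-window baseline, where the
#' baseline is the minimum SOFA in the 48 h before suspicion, 0 if
#' unmeasured). Time zero is the suspicion time of the earliest qualifying
#' pair.
#'
#' @param events Events of a single encounter, sorted by time.
#' @param encounter One-row encounter data.frame.
#' @param config A [criteria_config()].
#' @return A sepsis label (list with `encounter_id`, `definition`,
#'   `is_case`, `time_zero`, `components`).
#' @export
sepsis3_label <- function(events, encounter, config = criteria_config()) {
  events <- .filter_encounter_events(events, encounter, config)
  pairs <- detect_suspected_infection(events, config)
  if (nrow(pairs) == 0) return(.label(encounter$encounter_id, "SEPSIS3"))
  for (i in seq_len(nrow(pairs))) {
    s <- pairs$suspicion_time[i]
    w_lo <- s - config$sofa_window_before_hours * 3600
    w_hi <- s + config$sofa_window_after_hours * 3600
    times_pre <- unique(events$time[events$time >= w_lo & events$time < s])
    baseline <- if (length(times_pre) == 0) 0L else
      min(vapply(times_pre, function(t) sofa_score(events, t, config)$total, 0))
    times_win <- unique(events$time[events$time >= w_lo & events$time <= w_hi])
    for (t in sort(times_win)) {
      t <- as.POSIXct(t, origin = "1970-01-01", tz = "UTC")
      sc <- sofa_score(events, t, config)
      if (sc$total - baseline >= config$sofa_delta) {
        return(.label(encounter$encounter_id, "SEPSIS3", TRUE, s,
                      components = list(culture = pairs$culture_time[i],
                                        antibiotic = pairs$antibiotic_time[i],
                                        sofa_rise = t)))
      }
    }
  }
  .label(encounter$encounter_id, "SEPSIS3")
}

#' SEP-1 organ-dysfunction criteria fired in a rolling window
#'
#' Evaluates the SEP-1 severe-sepsis organ-dysfunction set in
#' `(at_time - window, at_time]`: SBP < 90, MAP < 65, SBP drop > 40 mmHg
#' from the encounter's pre-window maximum, lactate > 2.0, creatinine > 2.0,
#' bilirubin > 2.0, platelets < 100, INR > 1.5 (all strict). Urine output is
#' not modeled.
#'
#' @param events Events of a single encounter, sorted by time.
#' @param at_time Evaluation time (POSIXct).
#' @param window_hours Rolling window length in hours.
#' @param config A [criteria_config()].
#' @return Character vector of fired criteria (possibly empty).
#' @export
sep1_organ_dysfunction <- function(events, at_time, window_hours = 6,
                                   config = criteria_config()) {
  th <- config$thresholds
  from <- at_time - window_hours * 3600
  fired <- character()
  sbp <- .vals_in(events, "sbp_mmHg", from, at_time)
  if (any(sbp < th$sep1_sbp)) fired <- c(fired, "sbp_low")
  map <- .vals_in(events, "map_mmHg", from, at_time)
  if (any(map < th$sep1_map)) fired <- c(fired, "map_low")
  sbp_pre <- events$value[events$concept == "sbp_mmHg" & events$time <= from]
  if (length(sbp_pre) > 0 && length(sbp) > 0 &&
      any(max(sbp_pre) - sbp > th$sep1_sbp_drop)) {
    fired <- c(fired, "sbp_drop")
  }
  if (any(.vals_in(events, "lactate_mmol_L", from, at_time) > th$sep1_lactate))
    fired <- c(fired, "lactate")
  if (any(.vals_in(events, "creatinine_mg_dL", from, at_time) > th$sep1_creatinine))
    fired <- c(fired, "creatinine")
  if (any(.vals_in(events, "bilirubin_mg_dL", from, at_time) > th$sep1_bilirubin))
    fired <- c(fired, "bilirubin")
  if (any(.vals_in(events, "platelets_k_per_uL", from, at_time) < th$sep1_platelets))
    fired <- c(fired, "platelets")
  if (any(.vals_in(events, "inr", from, at_time) > th$sep1_inr))
    fired <- c(fired, "inr")
  fired
}

# Firing times of the individual SIRS criteria (used by the SEP-1 scan).
.sirs_fire_times <- function(events, th) {
  v <- events$value
  co <- events$concept
  list(
    temperature = events$time[co == "temperature_c" &
                                (v > th$sirs_temp_high | v < th$sirs_temp_low)],
    heart_rate = events$time[co == "heart_rate" & v > th$sirs_hr],
    resp_rate = events$time[co == "resp_rate" & v > th$sirs_rr],
    wbc = events$time[(co == "wbc_k_per_uL" &
                         (v > th$sirs_wbc_high | v < th$sirs_wbc_low)) |
                        (co == "band_pct" & v > th$sirs_band_pct)])
}

#' SEP-1 label for one encounter
#'
#' Case if and only if there is a time at which at least two SIRS criteria
#' and at least one SEP-1 organ-dysfunction criterion all fall inside the
#' rolling concurrency window. Time zero is the earliest such time, i.e. the
#' latest of the qualifying component times that completes the conjunction.
#'
#' @inheritParams sepsis3_label
#' @return A sepsis label.
#' @export
sep1_label <- function(events, encounter, config = criteria_config()) {
  events <- .filter_encounter_events(events, encounter, config)
  th <- config$thresholds
  sirs <- .sirs_fire_times(events, th)
  n_active <- sum(vapply(sirs, function(x) length(x) > 0, TRUE))
  if (n_active < 2) return(.label(encounter$encounter_id, "SEP1"))
  w <- config$sep1_window_hours * 3600
  # Conditions change only at firing times; scan candidate completion times.
  cand <- sort(unique(do.call(c, c(unname(sirs), list(events$time)))))
  for (t in cand) {
    t <- as.POSIXct(t, origin = "1970-01-01", tz = "UTC")
    n_sirs <- sum(vapply(sirs, function(x) any(x > t - w & x <= t), TRUE))
    if (n_sirs < 2) next
    od <- sep1_organ_dysfunction(events, t, config$sep1_window_hours, config)
    if (length(od) > 0) {
      comp <- lapply(sirs, function(x) {
        x <- x[x > t - w & x <= t]
        if (length(x) == 0) NULL else max(x)
      })
      comp <- comp[!vapply(comp, is.null, TRUE)]
      comp$organ_dysfunction <- t
      comp$criteria <- od
      return(.label(encounter$encounter_id, "SEP1", TRUE, t, comp))
    }
  }
  .label(encounter$encounter_id, "SEP1")
}

#' Qualifying antibiotic days relative to a blood culture
#'
#' A new antibiotic (no administration of the same agent in the prior two
#' calendar days) starting within the culture window must continue for at
#' least `qad_min_days` consecutive calendar days, bridging single-day gaps,
#' or until in-hospital death if that comes first.
#'
#' @param events Events of a single encounter, sorted by time.
#' @param culture_time Blood culture time (POSIXct).
#' @param encounter One-row encounter data.frame (uses `discharge_time` and
#'   `died_in_hospital`).
#' @param config A [criteria_config()].
#' @return A list with `qualifies` (logical) and `qad_start` (POSIXct or NA).
#' @export
qualifying_antibiotic_days <- function(events, culture_time, encounter,
                                       config = criteria_config()) {
  abx <- events[events$concept == "iv_antibiotic_admin", , drop = FALSE]
  no <- list(qualifies = FALSE, qad_start = .na_time())
  if (nrow(abx) == 0) return(no)
  abx_day <- calendar_day(abx$time)
  culture_day <- calendar_day(culture_time)

  # Candidate starts: first day of a "new" agent within the culture window.
  starts <- integer()
  for (nm in unique(abx$antibiotic_name)) {
    days_nm <- sort(unique(abx_day[abx$antibiotic_name == nm]))
    new_day <- days_nm[c(TRUE, diff(days_nm) > 2)]
    starts <- c(starts, new_day[abs(new_day - culture_day) <=
                                  config$ase_culture_window_days])
  }
  if (length(starts) == 0) return(no)
  all_days <- sort(unique(abx_day))
  death_day <- if (isTRUE(encounter$died_in_hospital))
    calendar_day(encounter$discharge_time) else NA_integer_

  for (d0 in sort(unique(starts))) {
    run <- all_days[all_days >= d0]
    if (length(run) == 0) next
    gap_ok <- c(TRUE, diff(run) <= config$qad_max_gap_days + 1)
    run <- run[cumprod(gap_ok) == 1]
    run_len <- run[length(run)] - d0 + 1
    qualifies <- run_len >= config$qad_min_days ||
      (!is.na(death_day) && death_day <= run[length(run)] + 1)
    if (qualifies) {
      start_t <- min(abx$time[abx_day == d0])
      return(list(qualifies = TRUE, qad_start = start_t))
    }
  }
  no
}

#' ASE organ-dysfunction criteria around a blood culture
#'
#' Evaluates the Adult Sepsis Event organ-dysfunction set within the
#' calendar-day window around the culture: vasopressor initiation,
#' mechanical-ventilation initiation, lactate >= 2.0 mmol/L, creatinine
#' doubling from baseline, bilirubin >= 2.0 mg/dL and doubled from baseline,
#' platelets < 100 k/uL with a baseline >= 100 and a decline of 50% or more.
#' Baselines are the best encounter values before the window (lowest
#' creatinine and bilirubin, highest platelets); baseline-dependent criteria
#' cannot fire without a baseline.
#'
#' @param events Events of a single encounter, sorted by time.
#' @param culture_time Blood culture time (POSIXct).
#' @param window_days Calendar-day half-width of the window.
#' @param config A [criteria_config()].
#' @return Named list of first firing times for the fired criteria.
#' @export
ase_organ_dysfunction <- function(events, culture_time, window_days = 2,
                                  config = criteria_config()) {
  th <- config$thresholds
  ev_day <- calendar_day(events$time)
  culture_day <- calendar_day(culture_time)
  in_win <- abs(ev_day - culture_day) <= window_days
  pre_win <- ev_day < culture_day - window_days
  fired <- list()
  first_time <- function(sel) {
    if (!any(sel)) NULL else min(events$time[sel])
  }
  add <- function(name, sel) {
    t <- first_time(sel)
    if (!is.null(t)) fired[[name]] <<- t
  }
  co <- events$concept
  v <- events$value
  add("vasopressor", in_win & co == "vasopressor_admin")
  add("mechanical_ventilation", in_win & co == "mech_vent_start")
  add("lactate", in_win & co == "lactate_mmol_L" & v >= th$ase_lactate)
  cr_base <- suppressWarnings(min(v[pre_win & co == "creatinine_mg_dL"]))
  if (is.finite(cr_base)) {
    add("creatinine", in_win & co == "creatinine_mg_dL" &
          v >= th$ase_creatinine_ratio * cr_base)
  }
  bili_base <- suppressWarnings(min(v[pre_win & co == "bilirubin_mg_dL"]))
  if (is.finite(bili_base)) {
    add("bilirubin", in_win & co == "bilirubin_mg_dL" &
          v >= th$ase_bilirubin & v >= th$ase_bilirubin_ratio * bili_base)
  }
  plt_base <- suppressWarnings(max(v[pre_win & co == "platelets_k_per_uL"]))
  if (is.finite(plt_base) && plt_base >= th$ase_platelets) {
    add("platelets", in_win & co == "platelets_k_per_uL" &
          v < th$ase_platelets &
          v <= (1 - th$ase_platelet_decline) * plt_base)
  }
  fired
}

#' Adult Sepsis Event label for one encounter
#'
#' Case if and only if a blood culture is accompanied by qualifying
#' antibiotic days and at least one ASE organ-dysfunction criterion inside
#' the culture window. With the default `ase_time_zero = "component_min"`,
#' time zero is the earliest among the culture time, the antibiotic-day
#' start, and the first organ-dysfunction time of the earliest qualifying
#' episode.
#'
#' @inheritParams sepsis3_label
#' @return A sepsis label.
#' @export
ase_label <- function(events, encounter, config = criteria_config()) {
  events <- .filter_encounter_events(events, encounter, config)
  cultures <- sort(.times_of(events, "blood_culture_order"))
  for (ct in cultures) {
    ct <- as.POSIXct(ct, origin = "1970-01-01", tz = "UTC")
    qad <- qualifying_antibiotic_days(events, ct, encounter, config)
    if (!qad$qualifies) next
    od <- ase_organ_dysfunction(events, ct, config$ase_culture_window_days,
                                config)
    if (length(od) == 0) next
    od_first <- do.call(c, od)
    t0 <- if (config$ase_time_zero == "culture") ct else
      min(ct, qad$qad_start, min(od_first))
    comp <- c(list(culture = ct, qad_start = qad$qad_start), od)
    return(.label(encounter$encounter_id, "ASE", TRUE, t0, comp))
  }
  .label(encounter$encounter_id, "ASE")
}

#' Phenotype a cohort under the three sepsis definitions
#'
#' Applies the selected definitions to every encounter's event stream and
#' returns one row per encounter and definition with case status, time zero
#' and a JSON provenance map of the criterion firing times that justify the
#' label.
#'
#' @param events Event data.frame for the cohort.
#' @param encounters Encounter data.frame.
#' @param definitions Subset of `c("SEPSIS3", "SEP1", "ASE")`.
#' @param config A [criteria_config()].
#' @return A data.frame `(encounter_id, definition, is_case, time_zero,
#'   components_json)`.
#' @export
phenotype_cohort <- function(events, encounters,
                             definitions = c("SEPSIS3", "SEP1", "ASE"),
                             config = criteria_config()) {
  definitions <- match.arg(definitions, several.ok = TRUE)
  fns <- list(SEPSIS3 = sepsis3_label, SEP1 = sep1_label, ASE = ase_label)
  ev_split <- split(events, factor(events$encounter_id,
                                   levels = encounters$encounter_id))
  empty <- events[0, , drop = FALSE]
  rows <- vector("list", nrow(encounters) * length(definitions))
  k <- 0
  for (i in seq_len(nrow(encounters))) {
    enc <- encounters[i, , drop = FALSE]
    ev <- ev_split[[enc$encounter_id]]
    if (is.null(ev)) ev <- empty
    for (d in definitions) {
      lab <- fns[[d]](ev, enc, config)
      k <- k + 1
      rows[[k]] <- data.frame(
        encounter_id = lab$encounter_id, definition = d,
        is_case = lab$is_case, time_zero = lab$time_zero,
        components_json = as.character(jsonlite::toJSON(
          lapply(lab$components, function(x) {
            if (inherits(x, "POSIXt")) format_timestamp(x) else x
          }), auto_unbox = TRUE)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
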