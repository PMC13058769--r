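cfg <- criteria_config()

test_that("sirs_count evaluates the four criteria in the rolling window", {
  ev <- mk_events("E1", list(c(1, "temperature_c", 39.0), c(1.5, "heart_rate", 100),
                             c(2, "resp_rate", 22), c(2.5, "wbc_k_per_uL", 13)))
  expect_equal(sirs_count(ev, ts(3), 6, cfg), 4L)
  expect_equal(sirs_count(ev, ts(20), 6, cfg), 0L)
  expect_equal(sirs_count(mk_events("E1", list(c(1, "temperature_c", 37.0))),
                          ts(2), 6, cfg), 0L)
  # window is half-open on the left: a measurement exactly `window` old is out
  expect_equal(sirs_count(ev, ts(7), 6, cfg), 3L)
  # each criterion counts once however many measurements satisfy it
  ev2 <- mk_events("E1", list(c(1, "heart_rate", 100), c(2, "heart_rate", 120)))
  expect_equal(sirs_count(ev2, ts(3), 6, cfg), 1L)
})

test_that("sofa_score maps worst window values through the organ tables", {
  empty_ev <- mk_events("E1", list(c(1, "heart_rate", 70)))[0, ]
  expect_equal(sofa_score(empty_ev, ts(1), cfg)$total, 0L)
  ev <- mk_events("E1", list(c(1, "platelets_k_per_uL", 90),
                             c(2, "bilirubin_mg_dL", 2.5)))
  sc <- sofa_score(ev, ts(3), cfg)
  expect_equal(sc$total, 4L)
  expect_equal(unname(sc$subscores[c("coagulation", "liver")]), c(2L, 2L))
  vaso <- mk_events("E1", list(c(1, "vasopressor_admin")))
  expect_gte(sofa_score(vaso, ts(2), cfg)$subscores[["cardiovascular"]], 3L)
  # worst (not latest) value in the lookback wins
  ev3 <- mk_events("E1", list(c(1, "platelets_k_per_uL", 40),
                              c(5, "platelets_k_per_uL", 200)))
  expect_equal(sofa_score(ev3, ts(6), cfg)$subscores[["coagulation"]], 3L)
})

test_that("suspected-infection pairing honours the two directional windows", {
  ev <- mk_events("E1", list(c(0, "blood_culture_order"),
                             list(ts(10), "iv_antibiotic_admin", NA, "cefepime")))
  p <- detect_suspected_infection(ev, cfg)
  expect_equal(nrow(p), 1L)
  expect_equal(p$suspicion_time, ts(0))

  ev2 <- mk_events("E1", list(list(ts(0), "iv_antibiotic_admin", NA, "cefepime"),
                              c(30, "blood_culture_order")))
  expect_equal(nrow(detect_suspected_infection(ev2, cfg)), 0L)

  ev3 <- mk_events("E1", list(c(0, "blood_culture_order")))
  expect_equal(nrow(detect_suspected_infection(ev3, cfg)), 0L)

  # antibiotic-first within 24 h qualifies, suspicion at the antibiotic
  ev4 <- mk_events("E1", list(list(ts(0), "iv_antibiotic_admin", NA, "cefepime"),
                              c(20, "blood_culture_order")))
  p4 <- detect_suspected_infection(ev4, cfg)
  expect_equal(p4$suspicion_time, ts(0))
})

test_that("sepsis3_label requires both suspicion and an acute SOFA rise", {
  enc <- mk_encounter()
  base <- list(c(0.5, "platelets_k_per_uL", 250),
               c(4, "blood_culture_order"),
               list(ts(5), "iv_antibiotic_admin", NA, "cefepime"))
  # SOFA delta 3 via platelet fall -> case at the suspicion time
  lab <- sepsis3_label(mk_events("E1", c(base, list(c(6, "platelets_k_per_uL", 40)))),
                       enc, cfg)
  expect_true(lab$is_case)
  expect_equal(lab$time_zero, ts(4))
  # delta 1 only -> not a case
  lab1 <- sepsis3_label(mk_events("E1", c(base, list(c(6, "creatinine_mg_dL", 1.5)))),
                        enc, cfg)
  expect_false(lab1$is_case)
  # SOFA rise without culture/antibiotics -> not a case
  lab2 <- sepsis3_label(mk_events("E1", list(c(0.5, "platelets_k_per_uL", 250),
                                             c(6, "platelets_k_per_uL", 40))),
                        enc, cfg)
  expect_false(lab2$is_case)
})

test_that("sep1 organ dysfunction uses strict thresholds", {
  expect_equal(sep1_organ_dysfunction(
    mk_events("E1", list(c(1, "lactate_mmol_L", 2.1))), ts(2), 6, cfg), "lactate")
  expect_length(sep1_organ_dysfunction(
    mk_events("E1", list(c(1, "lactate_mmol_L", 2.0))), ts(2), 6, cfg), 0L)
  fired <- sep1_organ_dysfunction(
    mk_events("E1", list(c(1, "sbp_mmHg", 85), c(1, "platelets_k_per_uL", 90))),
    ts(2), 6, cfg)
  expect_setequal(fired, c("sbp_low", "platelets"))
  # SBP drop needs a pre-window baseline more than 40 above the window value
  drop <- sep1_organ_dysfunction(
    mk_events("E1", list(c(0, "sbp_mmHg", 150), c(10, "sbp_mmHg", 105))),
    ts(10.5), 6, cfg)
  expect_equal(drop, "sbp_drop")
})

test_that("sep1_label fires on concurrent SIRS pair plus organ dysfunction", {
  enc <- mk_encounter()
  ev <- mk_events("E1", list(c(1, "temperature_c", 39.0), c(2, "heart_rate", 100),
                             c(3, "lactate_mmol_L", 2.5)))
  lab <- sep1_label(ev, enc, cfg)
  expect_true(lab$is_case)
  # time zero = latest component completing the conjunction
  expect_equal(lab$time_zero, ts(3))
  # no organ dysfunction -> not a case
  expect_false(sep1_label(mk_events("E1", list(c(1, "temperature_c", 39.0),
                                               c(2, "heart_rate", 100))),
                          enc, cfg)$is_case)
  # organ dysfunction outside the 6-h concurrency window -> not a case
  expect_false(sep1_label(mk_events("E1", list(c(1, "temperature_c", 39.0),
                                               c(2, "heart_rate", 100),
                                               c(20, "lactate_mmol_L", 2.5))),
                          enc, cfg)$is_case)
})

test_that("qualifying antibiotic days follow the 4-day rule with death exception", {
  enc <- mk_encounter(discharge = ts(24 * 6))
  abx_days <- function(days, name = "ceftriaxone") {
    mk_events("E1", lapply(days, function(d)
      list(ts(24 * d + 6), "iv_antibiotic_admin", NA, name)))
  }
  q <- qualifying_antibiotic_days(abx_days(0:3), ts(1), enc, cfg)
  expect_true(q$qualifies)
  expect_equal(q$qad_start, ts(6))
  # two days then routine live discharge -> does not qualify
  enc_live <- mk_encounter(discharge = ts(24 * 2 + 12))
  expect_false(qualifying_antibiotic_days(abx_days(0:1), ts(1), enc_live, cfg)$qualifies)
  # two days then in-hospital death -> qualifies
  enc_died <- mk_encounter(discharge = ts(24 * 2 + 12), died_in_hospital = TRUE)
  expect_true(qualifying_antibiotic_days(abx_days(0:1), ts(1), enc_died, cfg)$qualifies)
  # a single-day gap is bridged, a two-day gap breaks the run
  expect_true(qualifying_antibiotic_days(abx_days(c(0, 1, 3, 4)), ts(1), enc, cfg)$qualifies)
  expect_false(qualifying_antibiotic_days(abx_days(c(0, 3, 4, 5)), ts(1), enc, cfg)$qualifies)
  # the antibiotic must start within +/-2 calendar days of the culture
  expect_false(qualifying_antibiotic_days(abx_days(3:6), ts(1), enc, cfg)$qualifies)
})

test_that("ASE organ dysfunction applies baseline and inclusive-lactate rules", {
  culture <- ts(1, day = "2024-03-05")
  # creatinine doubling from a pre-window baseline
  ev <- mk_events("E1", list(
    list(ts(1, day = "2024-03-01"), "creatinine_mg_dL", 0.8),
    list(ts(2, day = "2024-03-05"), "creatinine_mg_dL", 1.7)))
  expect_named(ase_organ_dysfunction(ev, culture, 2, cfg), "creatinine")
  # platelet fall with baseline below 100 is gated out
  ev2 <- mk_events("E1", list(
    list(ts(1, day = "2024-03-01"), "platelets_k_per_uL", 90),
    list(ts(2, day = "2024-03-05"), "platelets_k_per_uL", 40)))
  expect_length(ase_organ_dysfunction(ev2, culture, 2, cfg), 0L)
  # lactate threshold is inclusive
  ev3 <- mk_events("E1", list(list(ts(2, day = "2024-03-05"), "lactate_mmol_L", 2.0)))
  expect_named(ase_organ_dysfunction(ev3, culture, 2, cfg), "lactate")
  # no baseline at all: ratio criteria cannot fire
  ev4 <- mk_events("E1", list(list(ts(2, day = "2024-03-05"), "creatinine_mg_dL", 3.0)))
  expect_length(ase_organ_dysfunction(ev4, culture, 2, cfg), 0L)
})

test_that("ase_label takes the earliest qualifying component as time zero", {
  enc <- mk_encounter(discharge = ts(24 * 6))
  bundle <- function(od_h) {
    c(list(c(4, "blood_culture_order"), list(ts(od_h), "lactate_mmol_L", 2.2)),
      lapply(0:3, function(d)
        list(ts(8 + 24 * d), "iv_antibiotic_admin", NA, "ceftriaxone")))
  }
  lab <- ase_label(mk_events("E1", bundle(6)), enc, cfg)
  expect_true(lab$is_case)
  expect_equal(lab$time_zero, ts(4))             # culture earliest
  lab2 <- ase_label(mk_events("E1", bundle(2)), enc, cfg)
  expect_equal(lab2$time_zero, ts(2))            # organ dysfunction earliest
  # culture + antibiotics but no organ dysfunction -> not a case
  no_od <- mk_events("E1", c(list(c(4, "blood_culture_order")),
                             lapply(0:3, function(d)
                               list(ts(8 + 24 * d), "iv_antibiotic_admin", NA,
                                    "ceftriaxone"))))
  expect_false(ase_label(no_od, enc, cfg)$is_case)
  # culture-anchored time zero variant
  cfg_c <- criteria_config(ase_time_zero = "culture")
  expect_equal(ase_label(mk_events("E1", bundle(2)), enc, cfg_c)$time_zero, ts(4))
})

test_that("labels are deterministic and time zero is stable under stream extension", {
  enc <- mk_encounter(discharge = ts(200))
  ev <- mk_events("E1", list(c(0.5, "platelets_k_per_uL", 250),
                             c(4, "blood_culture_order"),
                             list(ts(5), "iv_antibiotic_admin", NA, "cefepime"),
                             c(6, "platelets_k_per_uL", 40)))
  lab_a <- sepsis3_label(ev, enc, cfg)
  expect_identical(lab_a, sepsis3_label(ev, enc, cfg))
  # appending a later qualifying episode never moves the established time zero
  ext <- rbind(ev, mk_events("E1", list(c(100, "blood_culture_order"),
                                        list(ts(101), "iv_antibiotic_admin", NA,
                                             "cefepime"),
                                        c(102, "platelets_k_per_uL", 30))))
  expect_equal(sepsis3_label(ext, enc, cfg)$time_zero, lab_a$time_zero)
})

test_that("phenotyping recovers planted truth exactly on a small cohort", {
  coh <- generate_cohort(sim_config(n_encounters = 600, seed = 202))
  labs <- phenotype_cohort(coh$events, coh$encounters)
  m <- merge(labs, coh$truth, by = c("encounter_id", "definition"),
             suffixes = c(".det", ".tru"))
  expect_equal(nrow(m), 1800L)
  expect_equal(m$is_case.det, m$is_case.tru)
  cases <- m[m$is_case.tru, ]
  expect_gt(nrow(cases), 0L)
  expect_equal(cases$time_zero.det, cases$time_zero.tru)
  # provenance: every case carries a nonempty components map
  expect_true(all(nchar(labs$components_json[labs$is_case]) > 2))
})
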