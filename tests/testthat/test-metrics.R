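test_that("auroc matches the pairwise concordance oracle and handles ties", {
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(auroc(rep(5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(auroc(c(3, 1, 2, 4), c(0, 1, 0, 1)), 0.5)  # 2 of 4 pairs concordant
  expect_error(auroc(1:4, rep(1, 4)), "undefined")
  set.seed(1)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    y <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    s <- sample(1:5, n, replace = TRUE)  # heavy ties
    expect_equal(auroc(s, y), auroc_brute(s, y))
  }
  # invariance under strictly monotone score transforms
  set.seed(2)
  s <- rnorm(50); y <- rbinom(50, 1, 0.4)
  expect_equal(auroc(exp(2 * s + 1), y), auroc(s, y))
  # independent library cross-check
  expect_equal(auroc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("auprc is step-integrated average precision", {
  expect_equal(auprc(c(1, 2, 3), c(1, 1, 1)), 1.0)
  expect_equal(auprc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(auprc(c(4, 3, 2, 1), c(1, 0, 1, 0)), 1 * 0.5 + (2 / 3) * 0.5)
  expect_error(auprc(1:3, c(0, 0, 0)), "no positive")
  # a random score converges to prevalence
  set.seed(3)
  s <- runif(20000); y <- rbinom(20000, 1, 0.1)
  expect_lt(abs(auprc(s, y) - mean(y)), 0.02)
})

test_that("ece uses equal-count bins and the weighted absolute gap", {
  # perfectly calibrated degenerate case
  y <- rep(c(FALSE, TRUE), each = 500)
  expect_equal(ece(c(rep(0, 500), rep(1, 500)), y)$ece, 0)
  # single bin: |observed - predicted| directly
  r <- ece(rep(0.8, 5), c(1, 1, 0, 0, 0), n_bins = 1)
  expect_equal(r$ece, 0.4)
  expect_equal(r$bins$n, 5L)
  expect_error(ece(c(0.5, 1.2), c(0, 1)), "normalized")
  expect_error(ece(rep(0.5, 5), rep(c(0, 1), length.out = 5), n_bins = 10),
               "degeneracy")
  # equal-count binning: bin sizes differ by at most 1
  set.seed(4)
  r2 <- ece(runif(1005), rbinom(1005, 1, 0.3))
  expect_lte(diff(range(r2$bins$n)), 1)
  expect_equal(sum(r2$bins$n), 1005L)
})

test_that("decision curve closed forms hold exactly", {
  # perfect classifier: standardized net benefit 1 everywhere
  y <- rep(c(TRUE, FALSE), c(30, 70))
  s <- ifelse(y, 0.9, 0.05)
  dc <- decision_curve(s, y, pt_grid = seq(0.1, 0.8, by = 0.05))
  expect_true(all(abs(dc$standardized_net_benefit - 1) < 1e-12))
  expect_true(all(dc$treat_none == 0))
  # treat-all net benefit is exactly 0 at pt = prevalence
  pi_hat <- mean(y)
  dc2 <- decision_curve(runif(100), y, pt_grid = pi_hat)
  expect_lt(abs(dc2$treat_all), 1e-12)
  expect_error(decision_curve(runif(5), rep(FALSE, 5)), "undefined|no positive")
})

test_that("threshold sweep counts, boundaries and monotonicity", {
  inst <- data.frame(max_score_pre_t0 = c(50, 60, 70, 80, 10),
                     label = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  sw <- threshold_sweep(inst)
  expect_equal(sw$recall[sw$threshold == 0], 1)
  expect_equal(sw$flagged_fraction[sw$threshold == 0], 1)
  r50 <- sw[sw$threshold == 50, ]
  expect_equal(r50$n_flagged, 4L)
  expect_equal(r50$precision, 0.25)
  expect_equal(r50$nne, 4.0)
  # invariants over a generated sweep
  coh <- generate_cohort(sim_config(1500, seed = 8,
    sepsis_incidence_by_definition = c(SEPSIS3 = 0.1, SEP1 = 0, ASE = 0)))
  gi <- build_encounter_instances(coh$predictions, coh$truth, coh$encounters,
                                  "SEPSIS3")
  gsw <- threshold_sweep(gi)
  expect_true(all(diff(gsw$recall) <= 0))
  expect_true(all(diff(gsw$fpr) <= 0))
  expect_true(all(diff(gsw$flagged_fraction) <= 0))
  ok <- !is.na(gsw$nne)
  expect_true(all(abs(gsw$nne[ok] * gsw$precision[ok] - 1) < 1e-12))
})

test_that("youden top-left picks the point closest to (0,1)", {
  sw <- data.frame(threshold = c(1, 2), precision = c(0.5, 0.6),
                   recall = c(0.8, 0.9), fpr = c(0.2, 0.4),
                   nne = c(2, 1.7), n_flagged = c(10, 8),
                   flagged_fraction = c(0.5, 0.4))
  expect_equal(youden_top_left(sw)$threshold, 1)       # 0.283 beats 0.412
  expect_equal(youden_top_left(sw, style = "youden_j")$threshold, 1)
  # perfect point wins; degenerate one-row sweep returns itself
  sw2 <- rbind(sw, data.frame(threshold = 3, precision = 1, recall = 1,
                              fpr = 0, nne = 1, n_flagged = 5,
                              flagged_fraction = 0.25))
  expect_equal(youden_top_left(sw2)$threshold, 3)
  expect_equal(youden_top_left(sw[1, ])$threshold, 1)
  # ties break toward the higher threshold
  tie <- sw; tie$fpr <- c(0.2, 0.2); tie$recall <- c(0.8, 0.8)
  expect_equal(youden_top_left(tie)$threshold, 2)
})

test_that("predefined operating points follow the recall/precision rules", {
  inst <- data.frame(max_score_pre_t0 = c(95, 90, 60, 40, 30, 20, 10, 5),
                     label = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                               FALSE, FALSE, FALSE))
  ops <- select_operating_points(threshold_sweep(inst))
  # perfect separation: high-recall point is the highest threshold still
  # holding recall >= 0.8; the Youden point sits at (fpr 0, recall 1)
  expect_equal(ops$high_recall$threshold, 40)
  expect_equal(ops$high_recall$recall, 0.8)
  expect_equal(ops$youden_top_left$fpr, 0)
  expect_equal(ops$youden_top_left$recall, 1)
  # high recall = highest threshold with recall >= 0.8 on a toy sweep
  sw <- data.frame(threshold = 0:20,
                   precision = seq(0.05, 0.25, by = 0.01),
                   recall = seq(1, 0.6, by = -0.02),
                   fpr = seq(0.9, 0.1, by = -0.04))
  sw$nne <- 1 / sw$precision
  sw$n_flagged <- 100 - sw$threshold
  sw$flagged_fraction <- sw$n_flagged / 100
  ops2 <- select_operating_points(sw)
  expect_equal(ops2$high_recall$threshold, 10)  # recall 0.8 exactly at 10
  expect_equal(ops2$high_precision$threshold, 10)  # max recall s.t. prec >= .15
  # unattainable precision floor warns and returns NULL
  expect_warning(
    ops3 <- select_operating_points(sw, min_precision = 0.95),
    "precision")
  expect_null(ops3$high_precision)
})

test_that("stratified metrics mirror table semantics", {
  set.seed(9)
  inst <- data.frame(max_score_pre_t0 = runif(400, 0, 100),
                     label = rbinom(400, 1, 0.2) == 1,
                     sex = rep(c("F", "M"), each = 200),
                     ob = rep(c("no", "no", "no", "yes"), 100))
  inst$label[inst$ob == "yes"] <- FALSE  # a stratum with zero cases
  tab <- stratified_metrics(inst, c("sex", "ob"))
  ob_row <- tab[tab$stratum_field == "ob" & tab$stratum == "yes", ]
  expect_true(is.na(ob_row$auroc))
  expect_equal(ob_row$n_cases, 0L)
  # two identical strata give identical metrics
  inst2 <- inst[inst$sex == "F", ]
  inst2$dup <- rep(c("a", "b"), 100)
  inst2$max_score_pre_t0 <- rep(inst2$max_score_pre_t0[inst2$dup == "a"], each = 2)
  inst2$label <- rep(inst2$label[inst2$dup == "a"], each = 2)
  t2 <- stratified_metrics(inst2, "dup")
  expect_equal(t2$auroc[1], t2$auroc[2])
  expect_equal(t2$auprc[1], t2$auprc[2])
  expect_error(stratified_metrics(inst, "missing_field"), "not present")
})
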