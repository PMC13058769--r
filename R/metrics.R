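check_two_class <- function(labels) {
  if (length(unique(labels)) < 2) {
    stop("undefined metric: both classes must be present", call. = FALSE)
  }
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a random positive outscores a
#' random negative, with ties counted one half.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) outcome labels.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  check_two_class(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise integral of precision over recall at each distinct score cut
#' (average precision); no linear interpolation between operating points.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  P <- sum(labels)
  if (P == 0) stop("undefined metric: no positive instances", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(!y)
  n <- length(s)  # last index of each distinct score forms a PR cut
  cut <- c(which(s[-n] != s[-1]), n)
  precision <- tp[cut] / (tp[cut] + fp[cut])
  recall <- tp[cut] / P
  sum(diff(c(0, recall)) * precision)
}

#' Estimated calibration error with equal-count decile binning
#'
#' Bins the normalized scores into `n_bins` equal-count bins (deciles of the
#' empirical score distribution) and reports the prevalence-weighted mean
#' absolute gap between mean predicted risk and observed event rate.
#'
#' @param scores_normalized Scores in \[0, 1\] (raw 0-100 scores divided by
#'   100).
#' @param labels Logical (or 0/1) outcome labels.
#' @param n_bins Number of bins (default 10).
#' @return A list with `bins` (data.frame: bin, n, mean_predicted,
#'   observed_rate) and `ece`.
#' @export
ece <- function(scores_normalized, labels, n_bins = 10) {
  labels <- as.logical(labels)
  keep <- !is.na(scores_normalized) & !is.na(labels)
  s <- scores_normalized[keep]; y <- labels[keep]
  if (any(s < 0 | s > 1)) {
    stop("scores must be normalized to [0, 1]", call. = FALSE)
  }
  n <- length(s)
  if (n < n_bins) stop("bin degeneracy: fewer observations than bins",
                       call. = FALSE)
  ord <- order(s)
  bin <- integer(n)
  bin[ord] <- ceiling(seq_len(n) * n_bins / n)
  nb <- tabulate(bin, n_bins)
  mean_pred <- as.numeric(tapply(s, bin, mean))
  obs <- as.numeric(tapply(y, bin, mean))
  bins <- data.frame(bin = seq_len(n_bins), n = nb, mean_predicted = mean_pred,
                     observed_rate = obs)
  list(bins = bins, ece = sum(nb / n * abs(obs - mean_pred)))
}

#' Decision curve analysis
#'
#' Net benefit NB(pt) = TPR(pt) * pi - FPR(pt) * (1 - pi) * pt / (1 - pt)
#' with classification at normalized score >= pt, standardized net benefit
#' sNB = NB / pi, and treat-all / treat-none reference policies.
#'
#' @inheritParams ece
#' @param pt_grid Threshold probabilities in (0, 1).
#' @return A data.frame with one row per threshold probability.
#' @export
decision_curve <- function(scores_normalized, labels,
                           pt_grid = seq(0.01, 0.5, by = 0.01)) {
  labels <- as.logical(labels)
  keep <- !is.na(scores_normalized) & !is.na(labels)
  s <- scores_normalized[keep]; y <- labels[keep]
  stopifnot(all(pt_grid > 0), all(pt_grid < 1))
  pi_hat <- mean(y)
  if (pi_hat == 0) stop("undefined metric: no positive instances", call. = FALSE)
  P <- sum(y); N <- sum(!y)
  tpr <- vapply(pt_grid, function(pt) sum(s >= pt & y) / P, 0)
  fpr <- vapply(pt_grid, function(pt) sum(s >= pt & !y) / N, 0)
  w <- pt_grid / (1 - pt_grid)
  nb <- tpr * pi_hat - fpr * (1 - pi_hat) * w
  nb_all <- pi_hat - (1 - pi_hat) * w
  data.frame(threshold_probability = pt_grid, net_benefit = nb,
             standardized_net_benefit = nb / pi_hat,
             treat_all = nb_all, treat_all_standardized = nb_all / pi_hat,
             treat_none = 0)
}

#' Operating-point sweep over integer thresholds
#'
#' For every integer threshold 0-100, flags encounters whose maximum
#' pre-time-zero score reaches the threshold and reports precision, recall,
#' false-positive rate, number needed to evaluate (1/precision), flagged
#' count and flagged fraction. Instances without an eligible prediction are
#' dropped.
#'
#' @param instances Encounter instances from [build_encounter_instances()],
#'   or any data.frame with `max_score_pre_t0` and `label`.
#' @param thresholds Integer thresholds (default 0:100).
#' @return A data.frame with one row per threshold.
#' @export
threshold_sweep <- function(instances, thresholds = 0:100) {
  s <- instances$max_score_pre_t0
  y <- as.logical(instances$label)
  keep <- !is.na(s)
  s <- s[keep]; y <- y[keep]
  check_two_class(y)
  n <- length(s)
  P <- sum(y); N <- n - P
  s_pos <- sort(s[y]); s_all <- sort(s)
  n_flagged <- n - findInterval(thresholds - 1e-9, s_all)
  tp <- P - findInterval(thresholds - 1e-9, s_pos)
  fp <- n_flagged - tp
  precision <- ifelse(n_flagged > 0, tp / n_flagged, NA_real_)
  data.frame(threshold = thresholds, precision = precision,
             recall = tp / P, fpr = fp / N,
             nne = ifelse(!is.na(precision) & precision > 0, 1 / precision,
                          NA_real_),
             n_flagged = n_flagged, flagged_fraction = n_flagged / n)
}

#' Youden "top left" operating point
#'
#' The threshold whose ROC point lies closest to (0, 1) in Euclidean
#' distance, the default reading of the best sensitivity/specificity
#' trade-off; `style = "youden_j"` instead maximizes J = TPR - FPR. Ties are
#' broken toward the higher threshold.
#'
#' @param sweep A sweep from [threshold_sweep()].
#' @param style `"top_left"` (default) or `"youden_j"`.
#' @return The selected one-row sweep entry.
#' @export
youden_top_left <- function(sweep, style = c("top_left", "youden_j")) {
  style <- match.arg(style)
  stopifnot(nrow(sweep) > 0)
  crit <- if (style == "top_left") {
    sqrt(sweep$fpr^2 + (1 - sweep$recall)^2)
  } else {
    -(sweep$recall - sweep$fpr)
  }
  best <- which(crit <= min(crit) + 1e-12)
  sweep[best[which.max(sweep$threshold[best])], , drop = FALSE]
}

#' Select the predefined operating points
#'
#' High recall: the highest threshold with recall >= `min_recall`. High
#' precision: the threshold maximizing recall subject to precision >=
#' `min_precision` (ties toward the higher threshold). Plus the Youden
#' top-left point. Unattainable points are returned as `NULL` with a
#' warning.
#'
#' @param sweep A sweep from [threshold_sweep()].
#' @param min_recall Recall floor for the high-recall point (default 0.8).
#' @param min_precision Precision floor for the high-precision point
#'   (default 0.15).
#' @return A list with elements `high_recall`, `high_precision`,
#'   `youden_top_left` (each a one-row sweep entry or `NULL`).
#' @export
select_operating_points <- function(sweep, min_recall = 0.8,
                                    min_precision = 0.15) {
  stopifnot(nrow(sweep) > 0)
  hr <- sweep[sweep$recall >= min_recall, , drop = FALSE]
  high_recall <- if (nrow(hr) == 0) {
    warning("no threshold attains recall >= ", min_recall)
    NULL
  } else hr[which.max(hr$threshold), , drop = FALSE]
  hp <- sweep[!is.na(sweep$precision) & sweep$precision >= min_precision, ,
              drop = FALSE]
  high_precision <- if (nrow(hp) == 0) {
    warning("no threshold attains precision >= ", min_precision)
    NULL
  } else {
    best <- which(hp$recall >= max(hp$recall) - 1e-12)
    hp[best[which.max(hp$threshold[best])], , drop = FALSE]
  }
  list(high_recall = high_recall, high_precision = high_precision,
       youden_top_left = youden_top_left(sweep))
}

#' Stratified discrimination metrics
#'
#' AUROC/AUPRC within each level of each stratification field, with
#' detected/total counts. Strata containing a single class are reported with
#' `NA` metrics, mirroring the "NA" entries of clinical performance tables.
#'
#' @param instances Encounter instances.
#' @param strata_fields Character vector of column names to stratify by.
#' @return A data.frame `(stratum_field, stratum, n, n_cases, auroc, auprc)`.
#' @export
stratified_metrics <- function(instances, strata_fields) {
  missing <- setdiff(strata_fields, names(instances))
  if (length(missing) > 0) {
    stop("strata field(s) not present: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows <- list()
  for (f in strata_fields) {
    for (lev in sort(unique(as.character(instances[[f]])), na.last = TRUE)) {
      sel <- if (is.na(lev)) is.na(instances[[f]]) else
        !is.na(instances[[f]]) & as.character(instances[[f]]) == lev
      sub <- instances[sel & !is.na(instances$max_score_pre_t0), , drop = FALSE]
      a_roc <- tryCatch(auroc(sub$max_score_pre_t0, sub$label),
                        error = function(e) NA_real_)
      a_prc <- tryCatch({
        if (length(unique(sub$label)) < 2) NA_real_ else
          auprc(sub$max_score_pre_t0, sub$label)
      }, error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        stratum_field = f, stratum = as.character(lev), n = nrow(sub),
        n_cases = sum(sub$label), auroc = a_roc, auprc = a_prc,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
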