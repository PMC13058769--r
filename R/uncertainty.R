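#' Bootstrap configuration
#'
#' @param seed Integer seed (mandatory: published intervals must be
#'   reproducible).
#' @param n_boot Number of bootstrap replicates (default 1000; at least 100
#'   for reported intervals).
#' @param ci_level Confidence level (default 0.95).
#' @param method Interval method; `"percentile"` only.
#' @return A list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(seed, n_boot = 1000, ci_level = 0.95,
                             method = "percentile") {
  stopifnot(n_boot >= 100, ci_level > 0, ci_level < 1,
            method == "percentile")
  structure(list(seed = as.integer(seed), n_boot = as.integer(n_boot),
                 ci_level = ci_level, method = method),
            class = "bootstrap_config")
}

#' Patient-clustered bootstrap confidence interval
#'
#' Resamples patients with replacement, each draw carrying all of a sampled
#' patient's encounters (instances), and forms a percentile interval over
#' the replicate statistics. This respects within-patient correlation while
#' the statistic itself is computed over encounters.
#'
#' @param instances Instance data.frame carrying `patient_id`.
#' @param statistic Function mapping an instance data.frame to a scalar.
#' @param config A [bootstrap_config()].
#' @param name Name recorded on the estimate.
#' @return A list (`metric_estimate`): `name`, `point`, `ci_low`, `ci_high`,
#'   `n_boot`, `seed`, `n_failed`, `flagged` (TRUE when the statistic failed
#'   on more than 20% of replicates).
#' @export
clustered_bootstrap <- function(instances, statistic, config,
                                name = "statistic") {
  stopifnot(inherits(config, "bootstrap_config"))
  if (is.null(instances$patient_id)) {
    stop("instances must carry patient_id", call. = FALSE)
  }
  point <- statistic(instances)
  idx_by_patient <- split(seq_len(nrow(instances)), instances$patient_id)
  n_pat <- length(idx_by_patient)
  set.seed(config$seed)
  reps <- vapply(seq_len(config$n_boot), function(b) {
    sel <- sample.int(n_pat, n_pat, replace = TRUE)
    rows <- unlist(idx_by_patient[sel], use.names = FALSE)
    tryCatch(statistic(instances[rows, , drop = FALSE]),
             error = function(e) NA_real_)
  }, 0)
  n_failed <- sum(is.na(reps))
  alpha <- (1 - config$ci_level) / 2
  ci <- stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  if (!is.na(point) && (point < ci[1] || point > ci[2])) {
    warning("point estimate lies outside the percentile interval", call. = FALSE)
  }
  list(name = name, point = point, ci_low = ci[1], ci_high = ci[2],
       n_boot = config$n_boot, seed = config$seed, n_failed = n_failed,
       flagged = n_failed > 0.2 * config$n_boot)
}

#' Weekly performance drift table
#'
#' Groups encounter instances by ISO week of arrival and reports AUROC and
#' AUPRC per week; weeks containing a single class are reported with `NA`
#' metrics.
#'
#' @param instances Encounter instances carrying `arrival_time`.
#' @return A data.frame `(week, n, n_cases, auroc, auprc)` sorted by week.
#' @export
weekly_drift <- function(instances) {
  if (is.null(instances$arrival_time)) {
    stop("instances must carry arrival_time", call. = FALSE)
  }
  keep <- !is.na(instances$max_score_pre_t0)
  inst <- instances[keep, , drop = FALSE]
  week <- format(inst$arrival_time, "%G-W%V")
  rows <- lapply(sort(unique(week)), function(w) {
    sub <- inst[week == w, , drop = FALSE]
    single <- length(unique(sub$label)) < 2
    data.frame(week = w, n = nrow(sub), n_cases = sum(sub$label),
               auroc = if (single) NA_real_ else
                 auroc(sub$max_score_pre_t0, sub$label),
               auprc = if (single) NA_real_ else
                 auprc(sub$max_score_pre_t0, sub$label),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.one_row_list <- function(df) {
  if (is.null(df)) return(NULL)
  as.list(df[1, , drop = FALSE])
}

#' Assemble the evaluation report
#'
#' Combines cohort arithmetic and per-definition results into a single
#' machine-readable report. Incidence and case-mortality percentages are
#' recomputed here from the supplied counts via [incidence()], so the report
#' reproduces printed-table arithmetic exactly. Missing blocks are listed in
#' `$missing_blocks`; the report is still emitted.
#'
#' @param cohort A list with `n_total`, `n_included` and `exclusion_tally`
#'   (as from [apply_inclusion_filters()]).
#' @param definitions A named list (per definition) of lists with any of:
#'   `n_cases`, `n_deaths_in_cases`, `auroc`, `auprc` (metric estimates),
#'   `operating_points`, `lead_time`, `stratified`, `drift`, `censoring`.
#' @return A list of class `sepsis_eval_report`.
#' @export
assemble_report <- function(cohort, definitions) {
  stopifnot(!is.null(cohort$n_total), !is.null(cohort$n_included))
  if (cohort$n_total != cohort$n_included + sum(cohort$exclusion_tally %||% 0)) {
    stop("cohort counts do not conserve: total != included + excluded",
         call. = FALSE)
  }
  blocks <- c("n_cases", "n_deaths_in_cases", "auroc", "auprc",
              "operating_points", "lead_time", "stratified", "drift",
              "censoring")
  missing_blocks <- character()
  defs <- lapply(names(definitions), function(d) {
    x <- definitions[[d]]
    absent <- setdiff(blocks, names(x))
    if (length(absent) > 0) {
      missing_blocks <<- c(missing_blocks,
                           paste0(d, ":", absent))
    }
    out <- list(definition = d)
    if (!is.null(x$n_cases)) {
      out$n_cases <- x$n_cases
      out$incidence_pct <- incidence(x$n_cases, cohort$n_included)
      if (!is.null(x$n_deaths_in_cases)) {
        out$n_deaths_in_cases <- x$n_deaths_in_cases
        out$mortality_in_cases_pct <- incidence(x$n_deaths_in_cases, x$n_cases)
      }
    }
    for (nm in c("auroc", "auprc", "lead_time")) out[[nm]] <- x[[nm]]
    if (!is.null(x$operating_points)) {
      out$operating_points <- lapply(x$operating_points, .one_row_list)
    }
    for (nm in c("stratified", "drift")) {
      if (!is.null(x[[nm]])) out[[nm]] <- x[[nm]]
    }
    out$censoring <- x$censoring
    out
  })
  names(defs) <- names(definitions)
  structure(list(cohort = list(n_total = cohort$n_total,
                               n_included = cohort$n_included,
                               exclusion_tally = as.list(cohort$exclusion_tally)),
                 definitions = defs,
                 missing_blocks = missing_blocks),
            class = "sepsis_eval_report")
}

#' Write a report as JSON
#' @param report A report from [assemble_report()].
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, POSIXt = "ISO8601",
                       na = "null")
  invisible(path)
}
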