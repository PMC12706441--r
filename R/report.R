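# Dataset accounting, validation metrics on labelled data, and the
# config-driven end-to-end pipeline.

#' Stage-by-stage dataset accounting
#'
#' Tracks the two-step accounting used when cleaning a fraud-affected
#' survey: data-cleaning removals (duplicates, invalid records) come off
#' the started count first; fraud-score removals come off the scored count.
#' Percentages are rounded half-up to one decimal.
#'
#' @param n_started respondents who started the survey.
#' @param n_cleaning_removed removed during data cleaning.
#' @param n_fraud_removed removed by fraud scoring (out of the scored).
#' @return object of class `dataset_accounting` with `n_scored`
#'   (`n_started - n_cleaning_removed`), `n_included`
#'   (`n_scored - n_fraud_removed`), and the derived percentages.
#' @examples
#' account(1050, 135, 415)  # 915 scored, 500 included
#' @export
account <- function(n_started, n_cleaning_removed, n_fraud_removed) {
  if (n_started < 0 || n_cleaning_removed < 0 || n_fraud_removed < 0) {
    stopf("counts must be non-negative")
  }
  n_scored <- n_started - n_cleaning_removed
  if (n_scored < 0) stopf("cleaning removals exceed started count")
  n_included <- n_scored - n_fraud_removed
  if (n_included < 0) stopf("fraud removals exceed scored count")
  structure(list(
    n_started = as.integer(n_started),
    n_cleaning_removed = as.integer(n_cleaning_removed),
    n_scored = as.integer(n_scored),
    n_fraud_removed = as.integer(n_fraud_removed),
    n_included = as.integer(n_included),
    pct_fraud_of_scored = if (n_scored > 0)
      round_half_up(100 * n_fraud_removed / n_scored, 1) else NA_real_,
    pct_included_of_started = if (n_started > 0)
      round_half_up(100 * n_included / n_started, 1) else NA_real_
  ), class = "dataset_accounting")
}

#' @export
print.dataset_accounting <- function(x, ...) {
  cat(sprintf("started %d | cleaning -%d -> scored %d | fraud -%d (%.1f%%) -> included %d (%.1f%% of started)\n",
              x$n_started, x$n_cleaning_removed, x$n_scored,
              x$n_fraud_removed, x$pct_fraud_of_scored, x$n_included,
              x$pct_included_of_started))
  invisible(x)
}

#' Report a proportion as a half-up-rounded percentage
#'
#' @param numerator,denominator non-negative counts with
#'   `numerator <= denominator` and `denominator > 0`.
#' @param decimals decimal places (default 1).
#' @return `100 * numerator / denominator`, rounded half-up.
#' @examples
#' proportion_report(2547, 5598)  # 45.5
#' @export
proportion_report <- function(numerator, denominator, decimals = 1) {
  if (denominator <= 0) stopf("denominator must be positive")
  if (numerator < 0 || numerator > denominator) {
    stopf("numerator must lie in [0, denominator]")
  }
  round_half_up(100 * numerator / denominator, decimals)
}

#' Pipeline validation metrics against truth labels
#'
#' Treats exclusion of a fraudulent-archetype record (duplicator,
#' misrepresenter, or bot) as a true positive. Every record must carry a
#' truth label.
#'
#' @param final character vector of final decisions
#'   (`"INCLUDE"`/`"EXCLUDE"`).
#' @param truth character vector of truth archetypes, aligned with `final`.
#' @return list with confusion counts `TP`, `FP`, `TN`, `FN` and
#'   `sensitivity`, `specificity`.
#' @export
pipeline_metrics <- function(final, truth) {
  stopifnot(length(final) == length(truth))
  if (anyNA(truth)) stopf("all records need truth labels; %d missing",
                          sum(is.na(truth)))
  is_fraud <- truth != "genuine"
  excluded <- final == "EXCLUDE"
  TP <- sum(excluded & is_fraud)
  FN <- sum(!excluded & is_fraud)
  TN <- sum(!excluded & !is_fraud)
  FP <- sum(excluded & !is_fraud)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_)
}

#' Run the full screening pipeline from a YAML config
#'
#' The config either names an input file (`input:` with `schema:`) or a
#' synthetic cohort (`cohort:` with `preset`, optional overrides, and
#' `seed`), plus a criteria registry (`criteria:` preset name or YAML
#' path), control rules, calibration targets, and an output directory.
#' Emits `decisions.csv`, `calibration.csv`, `accounting.csv`, and
#' `run.log` (every removal logged once with a machine-readable reason).
#' Deterministic given the config and seed; on any stage error the partial
#' outputs are removed.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param out_dir overrides the config's `out_dir`.
#' @return the underlying [fraud_screen()] fit, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out_dir <- out_dir %||% cfg$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- file.path(out_dir, c("decisions.csv", "calibration.csv",
                                "accounting.csv", "run.log"))
  names(paths) <- c("decisions", "calibration", "accounting", "log")
  written <- character()
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }
  dataset <- run_stage("input", {
    if (!is.null(cfg$input)) {
      schema <- if (!is.null(cfg$schema)) read_survey_schema(cfg$schema)
                else default_schema()
      load_responses(cfg$input, schema,
                     fraud_onset_date = cfg$fraud_onset_date)
    } else if (!is.null(cfg$cohort)) {
      cc <- cfg$cohort
      preset <- cc$preset %||% "case1_like"
      over <- cc[setdiff(names(cc), "preset")]
      if (!is.null(cfg$seed) && is.null(over$seed)) over$seed <- cfg$seed
      generate_cohort(do.call(cohort_preset, c(list(name = preset), over)))
    } else {
      stopf("config names neither `input` nor `cohort`")
    }
  })
  registry <- run_stage("criteria", {
    cr <- cfg$criteria %||% "case1"
    if (is.character(cr) && file.exists(cr)) read_criteria_yaml(cr)$criteria
    else if (is.character(cr)) criteria_preset(cr)
    else cr
  })
  fit <- run_stage("screen", {
    args <- list(dataset = dataset, criteria = registry)
    if (!is.null(cfg$targets)) args$targets <- cfg$targets
    if (!is.null(cfg$dedup_keys)) args$dedup_keys <- cfg$dedup_keys
    if (!is.null(cfg$review_default)) args$review_default <- cfg$review_default
    if (isTRUE(cfg$controls_from_truth)) args$control_labels <-
      truth_controls(dataset)
    suppressWarnings(do.call(fraud_screen, args))
  })
  run_stage("report", {
    write_decisions(subset_dataset(dataset, fit$decisions$record_id),
                    fit$decisions, paths["decisions"])
    written <<- c(written, paths["decisions"])
    write_calibration(fit$calibration, paths["calibration"])
    written <<- c(written, paths["calibration"])
    acc <- fit$accounting
    utils::write.csv(data.frame(
      n_started = acc$n_started, n_cleaning_removed = acc$n_cleaning_removed,
      n_scored = acc$n_scored, n_fraud_removed = acc$n_fraud_removed,
      n_included = acc$n_included,
      pct_fraud_of_scored = acc$pct_fraud_of_scored,
      pct_included_of_started = acc$pct_included_of_started),
      paths["accounting"], row.names = FALSE)
    written <<- c(written, paths["accounting"])
    writeLines(fit$log, paths["log"])
  })
  invisible(fit)
}

# Dataset restricted to the named records (order preserved).
subset_dataset <- function(dataset, ids) {
  out <- dataset
  out$records <- dataset$records[match(ids, dataset$records$record_id), ,
                                 drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Control labels from synthetic truth archetypes
#'
#' For validating calibration on generated cohorts: genuine records become
#' negative controls and bots positive controls (the two archetypes email
#' rules would target), other archetypes stay unlabeled.
#'
#' @param dataset a labelled [survey_dataset()].
#' @return named control-label vector.
#' @export
truth_controls <- function(dataset) {
  ta <- dataset$records$truth_archetype
  out <- rep("unlabeled", length(ta))
  out[!is.na(ta) & ta == "genuine"] <- "negative"
  out[!is.na(ta) & ta == "bot"] <- "positive"
  stats::setNames(out, dataset$records$record_id)
}
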