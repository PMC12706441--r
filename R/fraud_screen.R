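# The central fit: clean -> evaluate criteria -> calibrate on controls ->
# select cut points -> bucket -> resolve review -> account.

#' Screen a survey dataset for fraudulent responses
#'
#' Fits the full tertiary fraud-removal procedure to a dataset. Records
#' failing structural validation and non-retained duplicate entries are
#' removed first as data cleaning (duplicates keep the earliest-started
#' entry). Every criterion in the registry is then evaluated on the scored
#' records; positive and negative controls are designated (from email rules
#' unless explicit labels are supplied); per-criterion sensitivity and
#' specificity are measured on the controls; include/exclude score cut
#' points are selected against the calibration targets; records are
#' bucketed, and the review bucket is resolved by the protective-free-text
#' / nonsensical-combination rules. No single criterion decides a record.
#'
#' @param dataset a [survey_dataset()].
#' @param criteria list of [criterion()] objects (default the `case1`
#'   preset).
#' @param control_rules a [control_rules()] object for email-based control
#'   designation.
#' @param control_labels optional explicit control labels (named
#'   `"positive"`/`"negative"`/`"unlabeled"` vector), overriding the email
#'   rules; synthetic truth labels may substitute here via
#'   [truth_controls()].
#' @param targets calibration targets: `min_specificity` (default 0.99),
#'   `min_sensitivity` (default 0.90).
#' @param thresholds optional pre-chosen `list(low_cut=, high_cut=)`;
#'   skips threshold selection (calibration is still reported when
#'   controls exist).
#' @param dedup_keys identifier fields for duplicate removal during
#'   cleaning, or `NULL` to skip deduplication.
#' @param review_default final decision for review records matching neither
#'   resolution clause (default `"EXCLUDE"`, conservative).
#' @return an object of class `fraud_screen`: list with `decisions` (one
#'   row per scored record), `removed` (cleaning removals with reasons),
#'   `results`, `calibration`, `thresholds`, `controls`, `accounting`,
#'   `metrics` (when truth labels are present), and `log`.
#' @seealso [predict.fraud_screen()], [summary.fraud_screen()],
#'   [run_pipeline()]
#' @examples
#' ds <- generate_cohort(cohort_preset("case1_like", n_records = 300,
#'                                     seed = 42))
#' fit <- suppressWarnings(fraud_screen(ds))
#' fit
#' coef(fit)
#' @export
fraud_screen <- function(dataset,
                         criteria = criteria_preset("case1"),
                         control_rules = surveyfraud::control_rules(),
                         control_labels = NULL,
                         targets = list(min_specificity = 0.99,
                                        min_sensitivity = 0.90),
                         thresholds = NULL,
                         dedup_keys = c("email", "phone"),
                         review_default = "EXCLUDE") {
  stopifnot(inherits(dataset, "survey_dataset"))
  cl <- match.call()
  log <- character()
  note <- function(fmt, ...) {
    log <<- c(log, sprintf("%s %s", format_utc(Sys.time()), sprintf(fmt, ...)))
  }
  n_started <- nrow(dataset$records)
  note("INFO start n=%d criteria=%d", n_started, length(criteria))

  # -- cleaning: structural validity, then duplicate entries --------------
  removed <- data.frame(record_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  viol <- validate_records(dataset)
  if (nrow(viol)) {
    bad <- unique(viol$record_id)
    reasons <- vapply(bad, function(id) {
      paste0("invalid:", paste(unique(viol$field[viol$record_id == id]),
                               collapse = "+"))
    }, character(1))
    removed <- rbind(removed, data.frame(record_id = bad, reason = reasons,
                                         stringsAsFactors = FALSE))
  }
  kept <- setdiff(dataset$records$record_id, removed$record_id)
  work <- subset_dataset(dataset, kept)
  if (!is.null(dedup_keys)) {
    groups <- find_duplicates(work, dedup_keys)
    dup_ids <- groups$record_id[!groups$retain]
    if (length(dup_ids)) {
      retained <- groups$record_id[groups$retain]
      of <- retained[groups$group[match(dup_ids, groups$record_id)]]
      removed <- rbind(removed, data.frame(
        record_id = dup_ids, reason = paste0("duplicate_of:", of),
        stringsAsFactors = FALSE))
      work <- subset_dataset(work, setdiff(work$records$record_id, dup_ids))
    }
  }
  for (i in seq_len(nrow(removed))) {
    note("REMOVE %s stage=cleaning reason=%s",
         removed$record_id[i], removed$reason[i])
  }
  n_cleaning <- nrow(removed)
  note("INFO cleaning removed=%d scored=%d", n_cleaning, nrow(work$records))

  # -- criteria and calibration ------------------------------------------
  results <- evaluate_criteria(work, criteria)
  scores <- total_score(results)
  controls <- if (!is.null(control_labels)) {
    lab <- control_labels[work$records$record_id]
    lab[is.na(lab)] <- "unlabeled"
    stats::setNames(lab, work$records$record_id)
  } else {
    designate_controls(work, control_rules)
  }
  note("INFO controls positive=%d negative=%d",
       sum(controls == "positive"), sum(controls == "negative"))
  calibration <- tryCatch(calibrate(results, controls), error = function(e) {
    if (is.null(thresholds)) stop(e)
    note("INFO calibration skipped: %s", conditionMessage(e))
    NULL
  })
  if (is.null(thresholds)) {
    thresholds <- select_thresholds(scores, controls, targets)
  } else {
    thresholds <- structure(list(low_cut = thresholds$low_cut,
                                 high_cut = thresholds$high_cut,
                                 degenerate = FALSE),
                            class = "score_thresholds")
  }
  note("INFO thresholds low=%g high=%g", thresholds$low_cut,
       thresholds$high_cut)

  # -- buckets and review resolution -------------------------------------
  decisions <- build_decisions(work, results, scores, thresholds,
                               review_default)
  for (i in which(decisions$final == "EXCLUDE")) {
    note("REMOVE %s stage=fraud reason=score:%g bucket=%s",
         decisions$record_id[i], decisions$total_score[i],
         decisions$bucket[i])
  }
  n_fraud <- sum(decisions$final == "EXCLUDE")
  acc <- account(n_started, n_cleaning, n_fraud)
  note("INFO included=%d excluded=%d", acc$n_included, n_fraud)

  fit <- structure(list(
    call = cl, criteria = criteria, results = results, scores = scores,
    controls = controls, calibration = calibration,
    thresholds = thresholds, decisions = decisions, removed = removed,
    accounting = acc, review_default = review_default, log = log,
    dataset = dataset), class = "fraud_screen")
  truth <- dataset$records$truth_archetype
  if (all(!is.na(truth))) {
    fit$metrics <- pipeline_metrics(final_decisions(fit)$final,
                                    final_decisions(fit)$truth)
  }
  fit
}

# Decision table for the scored records of `work`, resolving REVIEW via
# the free-text / consistency / duplicate clauses.
build_decisions <- function(work, results, scores, thresholds,
                            review_default) {
  buckets <- assign_bucket(scores, thresholds)
  evals <- vapply(results$specs, `[[`, character(1), "evaluator")
  ft_col <- which(evals == "freetext")[1]
  cv_col <- which(evals == "consistency")[1]
  dp_col <- which(evals == "duplicate")[1]
  get_col <- function(j) {
    if (is.na(j)) rep(FALSE, nrow(results$fired)) else results$fired[, j]
  }
  ft <- get_col(ft_col)
  cv <- get_col(cv_col)
  dp <- get_col(dp_col)
  n <- length(scores)
  final <- buckets
  reason <- rep(NA_character_, n)
  for (i in which(buckets == "REVIEW")) {
    res <- resolve_review(list(bucket = "REVIEW"), ft[i], as.integer(cv[i]),
                          dp[i],
                          list(default_review_outcome = review_default))
    final[i] <- res$final
    reason[i] <- res$reason
  }
  fired_names <- apply(results$fired, 1, function(r) {
    paste(colnames(results$fired)[r], collapse = ";")
  })
  data.frame(record_id = rownames(results$fired),
             total_score = unname(scores), bucket = buckets, final = final,
             fired_criteria = unname(fired_names), review_reason = reason,
             stringsAsFactors = FALSE)
}

# Full-cohort final decisions: scored records plus cleaning removals
# (cleaning-removed records count as excluded).
final_decisions <- function(fit) {
  recs <- fit$dataset$records
  dec <- fit$decisions[, c("record_id", "final")]
  if (nrow(fit$removed)) {
    dec <- rbind(dec, data.frame(record_id = fit$removed$record_id,
                                 final = "EXCLUDE",
                                 stringsAsFactors = FALSE))
  }
  dec$truth <- recs$truth_archetype[match(dec$record_id, recs$record_id)]
  dec
}

#' @export
print.fraud_screen <- function(x, ...) {
  cat("Survey fraud screen\n")
  print(x$accounting)
  print(x$thresholds)
  tab <- table(factor(x$decisions$bucket,
                      levels = c("INCLUDE", "REVIEW", "EXCLUDE")))
  cat(sprintf("buckets: INCLUDE=%d REVIEW=%d EXCLUDE=%d\n",
              tab["INCLUDE"], tab["REVIEW"], tab["EXCLUDE"]))
  if (!is.null(x$metrics)) {
    cat(sprintf("vs truth: sensitivity %.3f, specificity %.3f\n",
                x$metrics$sensitivity, x$metrics$specificity))
  }
  invisible(x)
}

#' Summarize a fraud screen
#'
#' @param object a `fraud_screen` fit.
#' @param ... unused.
#' @return a `summary.fraud_screen` list with the calibration table,
#'   thresholds, bucket and final-decision tabulations, accounting, and
#'   (when available) truth-label metrics.
#' @export
summary.fraud_screen <- function(object, ...) {
  structure(list(
    calibration = object$calibration,
    thresholds = object$thresholds,
    buckets = table(factor(object$decisions$bucket,
                           levels = c("INCLUDE", "REVIEW", "EXCLUDE"))),
    finals = table(factor(object$decisions$final,
                          levels = c("INCLUDE", "EXCLUDE"))),
    accounting = object$accounting,
    metrics = object$metrics,
    n_controls = c(positive = sum(object$controls == "positive"),
                   negative = sum(object$controls == "negative"))
  ), class = "summary.fraud_screen")
}

#' @export
print.summary.fraud_screen <- function(x, ...) {
  cat("Fraud screen summary\n\nPer-criterion control performance:\n")
  if (!is.null(x$calibration)) print(x$calibration) else cat("  (no controls)\n")
  cat(sprintf("\ncontrols: %d positive, %d negative\n",
              x$n_controls["positive"], x$n_controls["negative"]))
  print(x$thresholds)
  cat("\nbuckets:\n")
  print(x$buckets)
  cat("final decisions:\n")
  print(x$finals)
  cat("\naccounting: ")
  print(x$accounting)
  if (!is.null(x$metrics)) {
    cat(sprintf("vs truth: sensitivity %.3f, specificity %.3f (TP=%d FP=%d TN=%d FN=%d)\n",
                x$metrics$sensitivity, x$metrics$specificity,
                x$metrics$TP, x$metrics$FP, x$metrics$TN, x$metrics$FN))
  }
  invisible(x)
}

#' Criterion point weights of a fraud screen
#'
#' @param object a `fraud_screen` fit.
#' @param ... unused.
#' @return named numeric vector of signed fraud points.
#' @export
coef.fraud_screen <- function(object, ...) {
  stats::setNames(vapply(object$criteria, `[[`, numeric(1), "points"),
                  vapply(object$criteria, `[[`, character(1), "name"))
}

#' Apply a fitted fraud screen to new data
#'
#' Evaluates the fitted registry on `newdata` and buckets the resulting
#' scores with the already-selected cut points (no recalibration). Review
#' records are resolved by the same rules as in fitting. Duplicates within
#' `newdata` fire the duplicate criterion rather than being removed.
#'
#' @param object a `fraud_screen` fit.
#' @param newdata a [survey_dataset()] with the same schema.
#' @param ... unused.
#' @return decisions data frame (one row per record of `newdata`).
#' @export
predict.fraud_screen <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "survey_dataset"))
  results <- evaluate_criteria(newdata, object$criteria)
  scores <- total_score(results)
  build_decisions(newdata, results, scores, object$thresholds,
                  object$review_default)
}

#' Plot the fraud-score distribution of a fitted screen
#'
#' Histogram of total fraud scores with the include/exclude cut points.
#'
#' @param x a `fraud_screen` fit.
#' @param ... passed to [graphics::hist()].
#' @export
plot.fraud_screen <- function(x, ...) {
  graphics::hist(x$scores, breaks = 30, col = "grey85", border = "white",
                 main = "Total fraud scores", xlab = "signed fraud points",
                 ...)
  graphics::abline(v = x$thresholds$low_cut, col = "forestgreen", lwd = 2)
  graphics::abline(v = x$thresholds$high_cut, col = "firebrick", lwd = 2)
  graphics::legend("topright", lwd = 2, col = c("forestgreen", "firebrick"),
                   legend = c("include cut", "exclude cut"), bty = "n")
  invisible(x)
}
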