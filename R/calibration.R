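# Control-based calibration. Respondents with known institutional email
# domains serve as negative (assumed genuine) controls, those with highly
# suspicious pattern-based emails as positive (assumed fraudulent)
# controls; each criterion's sensitivity and specificity is measured on the
# controls and the include/exclude score cut points are chosen to hit
# target specificity and sensitivity.

#' Control designation rules
#'
#' @param negative_email_domains email domains treated as trusted
#'   (institutional) -- matching respondents become negative controls.
#' @param positive_email_patterns regular expressions applied to the email
#'   local part -- matching respondents become positive controls. The
#'   defaults capture digit-only locals and letter/digit alternation
#'   patterns.
#' @return list of class `control_rules`.
#' @export
control_rules <- function(negative_email_domains = .trusted_domains,
                          positive_email_patterns = c(
                            "^[0-9]{6,}$",
                            "^([a-z]{1,2}[0-9]{1,2}){3,}[a-z]{0,2}$")) {
  structure(list(negative_email_domains = tolower(negative_email_domains),
                 positive_email_patterns = positive_email_patterns),
            class = "control_rules")
}

#' Designate positive and negative controls from email rules
#'
#' Negative where the email domain is trusted; positive where the local
#' part matches a suspicious pattern; a record matching both is left
#' unlabeled with a warning; everything else is unlabeled.
#'
#' @param dataset a [survey_dataset()].
#' @param rules a [control_rules()] object.
#' @return named character vector over record ids with values
#'   `"positive"`, `"negative"`, `"unlabeled"`.
#' @export
designate_controls <- function(dataset, rules = control_rules()) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (!length(rules$negative_email_domains) ||
      !length(rules$positive_email_patterns)) {
    stopf("calibration impossible: empty control rule sets")
  }
  recs <- dataset$records
  email <- tolower(recs$email)
  has <- !is.na(email) & grepl("@", email, fixed = TRUE)
  domain <- ifelse(has, sub("^.*@", "", email), NA_character_)
  local <- ifelse(has, sub("@.*$", "", email), NA_character_)
  neg <- has & domain %in% rules$negative_email_domains
  pos <- rep(FALSE, nrow(recs))
  for (pat in rules$positive_email_patterns) {
    pos <- pos | (has & grepl(pat, local))
  }
  both <- neg & pos
  if (any(both)) {
    warnf("%d record(s) matched both control rules; left unlabeled",
          sum(both))
    neg[both] <- FALSE
    pos[both] <- FALSE
  }
  out <- rep("unlabeled", nrow(recs))
  out[neg] <- "negative"
  out[pos] <- "positive"
  stats::setNames(out, recs$record_id)
}

#' Sensitivity and specificity of one criterion on the controls
#'
#' Confusion counts are taken over labeled records only. For a suspicious
#' criterion, firing is the positive test; for a protective criterion the
#' polarity is inverted (not firing is the positive test), so that
#' sensitivity always measures detection of fraud. Undefined ratios are
#' reported as `NA`, never 0.
#'
#' @param fired logical vector of criterion results, aligned with `labels`.
#' @param labels control labels (`"positive"`/`"negative"`/`"unlabeled"`).
#' @param direction `"suspicious"` or `"protective"`.
#' @return one-row data frame: TP, FP, TN, FN, sensitivity, specificity.
#' @export
criterion_performance <- function(fired, labels,
                                  direction = c("suspicious", "protective")) {
  direction <- match.arg(direction)
  stopifnot(length(fired) == length(labels))
  pos <- labels == "positive"
  neg <- labels == "negative"
  if (!any(pos) && !any(neg)) {
    stopf("calibration error: no positive and no negative controls")
  }
  if (!any(pos)) stopf("calibration error: no positive controls")
  if (!any(neg)) stopf("calibration error: no negative controls")
  test_pos <- if (direction == "suspicious") fired else !fired
  TP <- sum(test_pos & pos)
  FN <- sum(!test_pos & pos)
  TN <- sum(!test_pos & neg)
  FP <- sum(test_pos & neg)
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  data.frame(TP = TP, FP = FP, TN = TN, FN = FN,
             sensitivity = sens, specificity = spec)
}

#' Calibration table over a criteria registry
#'
#' @param results a `criterion_results` object from [evaluate_criteria()].
#' @param labels control labels as from [designate_controls()] (named by
#'   record id, or positionally aligned).
#' @return data frame of class `calibration_table`: one row per criterion
#'   with direction, points, confusion counts, sensitivity, specificity.
#' @export
calibrate <- function(results, labels) {
  stopifnot(inherits(results, "criterion_results"))
  if (!is.null(names(labels))) {
    labels <- labels[rownames(results$fired)]
    labels[is.na(labels)] <- "unlabeled"
  }
  rows <- lapply(seq_along(results$specs), function(j) {
    sp <- results$specs[[j]]
    perf <- criterion_performance(results$fired[, j], labels, sp$direction)
    cbind(data.frame(criterion = sp$name, direction = sp$direction,
                     points = sp$points, stringsAsFactors = FALSE), perf)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' @export
print.calibration_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$sensitivity <- round(100 * y$sensitivity, 1)
  y$specificity <- round(100 * y$specificity, 1)
  names(y)[names(y) == "sensitivity"] <- "sens_pct"
  names(y)[names(y) == "specificity"] <- "spec_pct"
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write a calibration report CSV
#'
#' The header comment flags that control designation rests on assumed
#' email-rule controls, not verified ground truth.
#'
#' @param tab a `calibration_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(tab, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste("# per-criterion performance on email-rule controls;",
                   "control labels are assumptions, not verified truth"), con)
  utils::write.csv(as.data.frame(tab), con, row.names = FALSE)
  invisible(path)
}

#' Select include/exclude score cut points from control scores
#'
#' `high_cut` is the smallest observed score value such that at most
#' `1 - min_specificity` of negative controls score at or above it;
#' `low_cut` is the largest observed score value such that at most
#' `1 - min_sensitivity` of positive controls score at or below it. If no
#' observed value satisfies a constraint, or the cuts cross, the selection
#' is degenerate: both cuts collapse (to the midpoint when crossing) and a
#' degeneracy warning is emitted.
#'
#' @param scores numeric total fraud scores, aligned with `labels`.
#' @param labels control labels.
#' @param targets list with `min_specificity` (default 0.99) and
#'   `min_sensitivity` (default 0.90).
#' @return object of class `score_thresholds`: list with `low_cut`,
#'   `high_cut`, `degenerate`.
#' @export
select_thresholds <- function(scores, labels,
                              targets = list(min_specificity = 0.99,
                                             min_sensitivity = 0.90)) {
  stopifnot(length(scores) == length(labels))
  targets <- utils::modifyList(list(min_specificity = 0.99,
                                    min_sensitivity = 0.90), targets)
  pos <- scores[labels == "positive"]
  neg <- scores[labels == "negative"]
  if (!length(pos) || !length(neg)) {
    stopf("calibration error: need at least one positive and one negative control")
  }
  cand <- sort(unique(scores[labels %in% c("positive", "negative")]))
  alpha <- 1 - targets$min_specificity
  beta <- 1 - targets$min_sensitivity
  hi_ok <- vapply(cand, function(s) mean(neg >= s) <= alpha, logical(1))
  lo_ok <- vapply(cand, function(s) mean(pos <= s) <= beta, logical(1))
  degenerate <- FALSE
  high_cut <- if (any(hi_ok)) min(cand[hi_ok]) else {
    degenerate <- TRUE
    max(cand)
  }
  low_cut <- if (any(lo_ok)) max(cand[lo_ok]) else {
    degenerate <- TRUE
    min(cand)
  }
  if (low_cut > high_cut) {
    mid <- (low_cut + high_cut) / 2
    low_cut <- mid
    high_cut <- mid
    degenerate <- TRUE
  }
  if (degenerate) {
    warnf("degenerate threshold selection: controls do not support the targets; low_cut = %g, high_cut = %g",
          low_cut, high_cut)
  }
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 degenerate = degenerate),
            class = "score_thresholds")
}

#' @export
print.score_thresholds <- function(x, ...) {
  cat(sprintf("score thresholds: include <= %g < review < %g <= exclude%s\n",
              x$low_cut, x$high_cut,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}
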