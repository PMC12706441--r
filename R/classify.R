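# Classification: total fraud scores, three-way bucketing against the
# calibrated cut points, rule-based resolution of the review bucket, and
# the categorical low/medium/high risk profile with its sensitivity-
# analysis split.

#' Total fraud score per record
#'
#' Arithmetic sum of the signed points awarded by fired criteria.
#'
#' @param results a `criterion_results` object from [evaluate_criteria()].
#' @return named numeric vector over record ids.
#' @export
total_score <- function(results) {
  stopifnot(inherits(results, "criterion_results"))
  rowSums(results$points)
}

#' Assign include/exclude/review buckets
#'
#' Scores at or below `low_cut` are included, at or above `high_cut`
#' excluded, and strictly between the cuts marked for review. When the cuts
#' coincide the review band is empty and the boundary score is excluded
#' (the conservative side).
#'
#' @param score numeric vector of total fraud scores.
#' @param thresholds a `score_thresholds` object from [select_thresholds()]
#'   (or any list with `low_cut <= high_cut`).
#' @return character vector in `INCLUDE`, `EXCLUDE`, `REVIEW`.
#' @export
assign_bucket <- function(score, thresholds) {
  if (thresholds$low_cut > thresholds$high_cut) {
    stopf("invalid thresholds: low_cut > high_cut")
  }
  ifelse(score >= thresholds$high_cut, "EXCLUDE",
         ifelse(score <= thresholds$low_cut, "INCLUDE", "REVIEW"))
}

#' Resolve a review-bucket decision to a final include/exclude
#'
#' Automates the manual review stage by its stated rules: protective free
#' text with no nonsensical-combination violations includes; any violation
#' or a duplicate flag excludes; otherwise the configured default applies
#' (exclude, conservatively, unless overridden).
#'
#' @param decision list or one-row data frame with at least `bucket`; must
#'   be `"REVIEW"`.
#' @param freetext_ok did the free-text protective criterion fire?
#' @param n_violations number of fired nonsensical-combination rules.
#' @param duplicate is the record a non-retained duplicate?
#' @param params list; `default_review_outcome` (default `"EXCLUDE"`).
#' @return list with `final` (`"INCLUDE"`/`"EXCLUDE"`) and `reason`.
#' @export
resolve_review <- function(decision, freetext_ok, n_violations,
                           duplicate = FALSE, params = list()) {
  if (is.data.frame(decision)) decision <- as.list(decision)
  if (!identical(decision$bucket, "REVIEW")) {
    stopf("resolve_review called on a %s decision", decision$bucket)
  }
  default <- params$default_review_outcome %||% "EXCLUDE"
  if (n_violations > 0 || duplicate) {
    reason <- if (n_violations > 0) "nonsensical_combination" else "duplicate"
    return(list(final = "EXCLUDE", reason = reason))
  }
  if (freetext_ok) {
    return(list(final = "INCLUDE", reason = "protective_freetext"))
  }
  list(final = default, reason = "review_default")
}

.risk_signals <- c("multiple_screening", "no_phn", "cross_inconsistent",
                   "straightlining", "gift_card_interest", "low_engagement")
.high_weight_signals <- c("multiple_screening", "gift_card_interest",
                          "cross_inconsistent")

#' Categorize fraud likelihood from the six screening signals
#'
#' The signals are: more than one screening attempt; failure to provide a
#' personal health number; inconsistent information across surveys and
#' screening; the same response to every standard-scale question; notably
#' high interest in gift cards; and low engagement with the program. The
#' first, third, and fifth are high-weight. A record is `high` when a
#' high-weight signal fires together with at least one other signal (or two
#' high-weight signals fire), `medium` when two or more signals fire
#' without meeting the high rule, `low` otherwise.
#'
#' @param signals logical matrix or data frame with the six named columns
#'   (`multiple_screening`, `no_phn`, `cross_inconsistent`,
#'   `straightlining`, `gift_card_interest`, `low_engagement`), one row per
#'   record; or a single named logical vector.
#' @return data frame with `category` (`low`/`medium`/`high`) and
#'   `fired_signals` (semicolon-joined names), one row per input row.
#' @export
categorize_risk <- function(signals) {
  if (is.vector(signals) && !is.list(signals)) {
    signals <- as.data.frame(as.list(signals))
  }
  signals <- as.data.frame(signals)
  missing <- setdiff(.risk_signals, names(signals))
  if (length(missing)) {
    stopf("missing risk signals: %s", paste(missing, collapse = ", "))
  }
  m <- as.matrix(signals[, .risk_signals, drop = FALSE])
  mode(m) <- "logical"
  m[is.na(m)] <- FALSE
  nh <- rowSums(m[, .high_weight_signals, drop = FALSE])
  ns <- rowSums(m)
  category <- ifelse(nh >= 1 & ns >= 2, "high",
                     ifelse(ns >= 2, "medium", "low"))
  fired <- apply(m, 1, function(r) {
    paste(.risk_signals[r], collapse = ";")
  })
  data.frame(category = category, fired_signals = fired,
             stringsAsFactors = FALSE)
}

#' Split records for the medium-likelihood sensitivity analysis
#'
#' Subset A keeps low-likelihood records only; subset B keeps low and
#' medium; high-likelihood records appear in neither.
#'
#' @param categories character vector in `low`/`medium`/`high`, named by
#'   record id (or positional).
#' @return list with `primary` (low only) and `extended` (low + medium)
#'   index/name vectors.
#' @export
sensitivity_split <- function(categories) {
  if (anyNA(categories)) stopf("missing category for some records")
  bad <- setdiff(unique(categories), c("low", "medium", "high"))
  if (length(bad)) stopf("unknown categories: %s", paste(bad, collapse = ", "))
  ids <- names(categories) %||% seq_along(categories)
  list(primary = ids[categories == "low"],
       extended = ids[categories %in% c("low", "medium")])
}
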