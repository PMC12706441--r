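# Independent brute-force oracles. These deliberately re-derive each rule
# from its written definition, without reusing package internals, so the
# implementation is checked against an independent path.

# O(n^2) pairwise duplicate detection with transitive closure.
oracle_duplicates <- function(records, keys) {
  n <- nrow(records)
  norm <- function(x) {
    x <- gsub("[[:space:]]+", "", tolower(as.character(x)))
    x[!is.na(x) & x == ""] <- NA
    x
  }
  adj <- matrix(FALSE, n, n)
  for (k in keys) {
    v <- norm(records[[k]])
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && !is.na(v[i]) && !is.na(v[j]) && v[i] == v[j]) {
          adj[i, j] <- TRUE
        }
      }
    }
  }
  # transitive closure via repeated squaring of the reachability relation
  reach <- adj | diag(n) > 0
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- rep(NA_integer_, n)
  g <- 0
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      g <- g + 1
      comp[which(reach[i, ])] <- g
    }
  }
  sizes <- table(comp)
  in_group <- comp %in% as.integer(names(sizes)[sizes > 1])
  dup <- rep(FALSE, n)
  for (gg in unique(comp[in_group])) {
    members <- which(comp == gg)
    first <- members[order(records$started_at[members], members)][1]
    dup[setdiff(members, first)] <- TRUE
  }
  list(in_group = records$record_id[in_group],
       duplicates = records$record_id[dup])
}

# Exhaustive enumeration of qualifying time-sorted runs.
oracle_batch <- function(ids, times, window_s, min_count, keyvals = NULL) {
  flag_subset <- function(ids, times) {
    ord <- order(times)
    ids <- ids[ord]; times <- as.numeric(times[ord])
    flagged <- character()
    n <- length(ids)
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        if (b - a + 1 < min_count) next
        if (b > n) next
        seg <- a:b
        if (all(diff(times[seg]) <= window_s)) {
          flagged <- union(flagged, ids[seg])
        }
      }
    }
    flagged
  }
  if (is.null(keyvals)) return(flag_subset(ids, times))
  keyvals <- gsub("[[:space:]]+", "", tolower(as.character(keyvals)))
  out <- character()
  for (v in unique(keyvals[!is.na(keyvals) & keyvals != ""])) {
    sel <- which(!is.na(keyvals) & keyvals == v)
    out <- union(out, flag_subset(ids[sel], times[sel]))
  }
  out
}

# Literal transcription of the suspicious-email rule.
oracle_email <- function(email, name, digit_frac = 0.5, alt_runs = 3) {
  if (is.na(email) || !nzchar(email)) return(FALSE)
  if (!grepl("@", email, fixed = TRUE)) return(TRUE)
  local <- tolower(sub("@.*$", "", email))
  ch <- strsplit(local, "")[[1]]
  type <- ifelse(grepl("[0-9]", ch), "d", ifelse(grepl("[a-z]", ch), "l", NA))
  type <- type[!is.na(type)]
  if (!length(type)) return(TRUE)
  if (mean(type == "d") > digit_frac) return(TRUE)
  toks <- if (is.na(name)) character() else
    strsplit(gsub("[^a-z ]", "", tolower(name)), " +")[[1]]
  toks <- toks[!is.na(toks) & nzchar(toks)]
  cands <- unique(c(toks, paste(toks, collapse = ""),
                    paste(substr(toks, 1, 1), collapse = "")))
  cands <- cands[nchar(cands) >= 3]
  shared <- FALSE
  for (cd in cands) {
    for (s in 1:(nchar(cd) - 2)) {
      if (grepl(substr(cd, s, s + 2), local, fixed = TRUE)) shared <- TRUE
    }
  }
  if (shared) return(FALSE)
  runs <- rle(type)
  (length(runs$values) - 1) >= alt_runs
}

# Brute-force 2x2 tabulation for criterion performance.
oracle_tabulate <- function(fired, labels, direction) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(fired)) {
    if (!labels[i] %in% c("positive", "negative")) next
    test_pos <- if (direction == "suspicious") fired[i] else !fired[i]
    if (labels[i] == "positive" && test_pos) tp <- tp + 1
    if (labels[i] == "positive" && !test_pos) fn <- fn + 1
    if (labels[i] == "negative" && !test_pos) tn <- tn + 1
    if (labels[i] == "negative" && test_pos) fp <- fp + 1
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

# Literal transcription of the stated low/medium/high rule.
oracle_risk <- function(sig) {
  high_weight <- c("multiple_screening", "gift_card_interest",
                   "cross_inconsistent")
  nh <- sum(unlist(sig[high_weight]))
  ns <- sum(unlist(sig))
  fires_high_with_other <- nh >= 1 && (ns - nh) >= 1
  two_high <- nh >= 2
  if (fires_high_with_other || two_high) "high"
  else if (ns >= 2) "medium"
  else "low"
}

# Small hand-built dataset for plumbing tests.
tiny_dataset <- function() {
  recs <- data.frame(
    record_id = c("r1", "r2", "r3"),
    started_at = c("2020-09-01T10:00:00Z", "2020-09-02T11:00:00Z",
                   "2020-10-07T09:00:00Z"),
    submitted_at = c("2020-09-01T10:20:00Z", "2020-09-02T11:30:00Z",
                     "2020-10-07T09:05:00Z"),
    email = c("jane.smith@ubc.ca", "a@x.org", "q1w2e3r4@mail.com"),
    name = c("Jane Smith", "Alex Ong", "Bob Lee"),
    remuneration_requested = c(FALSE, TRUE, TRUE),
    honeypot_value = c("", "", "x"),
    captcha_score = c(0.9, 0.8, 0.2),
    screening_attempts = c(1L, 1L, 3L),
    specialty = c("family_medicine", "obgyn", "mfm_subspecialist"),
    college = c("CFPC", "RCPSC", "CFPC"),
    ft_other_services = c("I also provide procedural abortion at a second clinic",
                          "We offer telehealth consults for rural patients each week",
                          ""),
    stringsAsFactors = FALSE
  )
  survey_dataset(recs, schema = surveyfraud:::default_schema(),
                 fraud_onset_date = "2020-10-06T00:00:00Z")
}
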