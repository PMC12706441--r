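# Fraud criteria. Each criterion is a named, signed point weight attached
# to a deterministic evaluator: protective criteria carry negative points
# (plausible free text, not requesting remuneration, pre-onset submission),
# suspicious criteria positive points (honeypot hits, nonsensical answer
# combinations, pattern emails, sub-threshold completion times, batch
# membership). No single criterion decides inclusion; scores aggregate.

#' Define a fraud criterion
#'
#' @param name unique criterion name.
#' @param direction `"protective"` or `"suspicious"`.
#' @param points signed weight added to a record's total fraud score when
#'   the criterion fires; its sign must match the direction (negative for
#'   protective) and may not be zero. Larger magnitudes encode stronger
#'   assumed predictive value.
#' @param evaluator evaluator id; one of `"honeypot"`, `"captcha"`,
#'   `"completion_time"`, `"email_pattern"`, `"duplicate"`, `"batch"`,
#'   `"consistency"`, `"freetext"`, `"no_remuneration"`, `"pre_onset"`,
#'   `"post_onset"`, `"screening_attempts"`, `"registry_unverified"`,
#'   `"straightline"`.
#' @param params evaluator-specific parameter list.
#' @return an object of class `fraud_criterion`.
#' @export
criterion <- function(name, direction = c("suspicious", "protective"),
                      points, evaluator, params = list()) {
  direction <- match.arg(direction)
  if (points == 0) stopf("criterion '%s': points must be non-zero", name)
  if (direction == "protective" && points > 0) {
    stopf("criterion '%s': protective criteria need negative points", name)
  }
  if (direction == "suspicious" && points < 0) {
    stopf("criterion '%s': suspicious criteria need positive points", name)
  }
  if (!evaluator %in% names(.evaluators)) {
    stopf("config error: unknown evaluator '%s'", evaluator)
  }
  structure(list(name = name, direction = direction, points = points,
                 evaluator = evaluator, params = params),
            class = "fraud_criterion")
}

#' Declare a nonsensical answer-combination rule
#'
#' A conjunction of clauses over declared answer fields; when every clause
#' holds the combination is deemed nonsensical (for example a maternal-fetal
#' medicine subspecialist registered with a family-practice college).
#'
#' @param name rule name.
#' @param clauses list of clauses, each `list(field=, op=, value=)` with op
#'   one of `"eq"`, `"ne"`, `"in"`, `"lt"`, `"le"`, `"gt"`, `"ge"`.
#' @return an object of class `consistency_rule`.
#' @export
consistency_rule <- function(name, clauses) {
  ok_ops <- c("eq", "ne", "in", "lt", "le", "gt", "ge")
  for (cl in clauses) {
    if (is.null(cl$field) || is.null(cl$op) || is.null(cl$value)) {
      stopf("rule '%s': each clause needs field, op, value", name)
    }
    if (!cl$op %in% ok_ops) stopf("rule '%s': unknown op '%s'", name, cl$op)
  }
  structure(list(name = name, clauses = clauses), class = "consistency_rule")
}

#' Default nonsensical-combination rules for the shipped demographic schema
#' @return list of [consistency_rule()] objects.
#' @export
default_consistency_rules <- function() {
  list(
    consistency_rule("mfm_cfpc", list(
      list(field = "specialty", op = "eq", value = "mfm_subspecialist"),
      list(field = "college", op = "eq", value = "CFPC"))),
    consistency_rule("np_rcpsc", list(
      list(field = "specialty", op = "eq", value = "nurse_practitioner"),
      list(field = "college", op = "eq", value = "RCPSC")))
  )
}

# Validate that every rule references declared fields; a config-time check,
# not an evaluation-time one.
validate_rules <- function(rules, schema) {
  known <- question_ids(schema)
  for (r in rules) {
    for (cl in r$clauses) {
      if (!cl$field %in% known) {
        stopf("config error: rule '%s' references unknown field '%s'",
              r$name, cl$field)
      }
    }
  }
  invisible(TRUE)
}

#' Evaluate nonsensical-combination rules on one record
#'
#' @param record one-row data frame or named list of answers.
#' @param rules list of [consistency_rule()] objects.
#' @return character vector of the names of the rules whose clause
#'   conjunction holds.
#' @export
consistency_violations <- function(record, rules) {
  if (is.data.frame(record)) record <- as.list(record)
  fired <- vapply(rules, function(r) {
    all(vapply(r$clauses, function(cl) {
      v <- record[[cl$field]]
      if (is.null(v) || length(v) == 0 || is.na(v)) return(FALSE)
      switch(cl$op,
        eq = as.character(v) == as.character(cl$value),
        ne = as.character(v) != as.character(cl$value),
        "in" = as.character(v) %in% as.character(cl$value),
        lt = as.numeric(v) < as.numeric(cl$value),
        le = as.numeric(v) <= as.numeric(cl$value),
        gt = as.numeric(v) > as.numeric(cl$value),
        ge = as.numeric(v) >= as.numeric(cl$value))
    }, logical(1)))
  }, logical(1))
  vapply(rules[fired], `[[`, character(1), "name")
}

#' Flag a suspicious email address pattern
#'
#' Encodes the qualitative description of fraudster emails: mostly-numeric
#' local parts, or local parts with no relationship to the respondent's
#' name that alternate between digit runs and letter runs. Fires when the
#' digit fraction of the local part exceeds `digit_frac` (default 0.5), or
#' when no case-insensitive substring of length >= 3 is shared between the
#' local part and the name tokens/initials while the number of digit-run /
#' letter-run alternations is at least `alt_runs` (default 3). A
#' syntactically malformed address (no `@`) fires as suspicious; a missing
#' address does not fire.
#'
#' @param email,name character scalars (vectorized over records).
#' @param params list overriding `digit_frac`, `alt_runs`, `min_sub`.
#' @return logical vector.
#' @export
email_pattern_flag <- function(email, name = NA_character_, params = list()) {
  p <- utils::modifyList(list(digit_frac = 0.5, alt_runs = 3, min_sub = 3),
                         params)
  n <- max(length(email), length(name))
  email <- rep_len(as.character(email), n)
  name <- rep_len(as.character(name), n)
  vapply(seq_len(n), function(i) {
    e <- email[i]
    if (is.na(e) || !nzchar(e)) return(FALSE)
    if (!grepl("@", e, fixed = TRUE)) return(TRUE)  # malformed
    local <- tolower(sub("@.*$", "", e))
    chars <- strsplit(local, "")[[1]]
    is_d <- grepl("[0-9]", chars)
    is_l <- grepl("[a-z]", chars)
    alnum <- is_d | is_l
    if (!any(alnum)) return(TRUE)
    digit_frac <- sum(is_d) / sum(alnum)
    if (digit_frac > p$digit_frac) return(TRUE)
    # name overlap: any >=3-char substring of a name token (or the
    # concatenated initials/full name) occurring in the local part
    nm <- name[i]
    overlap <- FALSE
    if (!is.na(nm) && nzchar(nm)) {
      toks <- tokenize_words(nm)
      cand <- unique(c(toks, paste(toks, collapse = ""),
                       paste(substring(toks, 1, 1), collapse = "")))
      cand <- cand[nchar(cand) >= p$min_sub]
      for (cd in cand) {
        for (s in seq_len(nchar(cd) - p$min_sub + 1)) {
          if (grepl(substring(cd, s, s + p$min_sub - 1), local,
                    fixed = TRUE)) {
            overlap <- TRUE
            break
          }
        }
        if (overlap) break
      }
    }
    if (overlap) return(FALSE)
    type <- ifelse(is_d[alnum], "d", "l")
    runs <- rle(type)
    alternations <- length(runs$values) - 1
    alternations >= p$alt_runs
  }, logical(1))
}

#' Flag sub-threshold completion time
#'
#' Strictly less than the threshold fires; a record that takes exactly the
#' threshold does not.
#'
#' @param duration_s non-negative duration(s) in seconds.
#' @param threshold_s minimum acceptable completion time (for example 300 s
#'   for a short clinician survey, 800 s for a longer patient survey).
#' @return logical vector; `NA` durations give `FALSE`.
#' @export
completion_time_flag <- function(duration_s, threshold_s) {
  !is.na(duration_s) & duration_s < threshold_s
}

#' Group duplicate respondents by shared identifiers
#'
#' Records sharing any normalized value (lowercased, whitespace stripped)
#' of any listed identifier key are grouped transitively; within each group
#' the earliest-started record is marked `retain` and the rest are
#' duplicates. Missing or empty identifiers never match.
#'
#' @param dataset a [survey_dataset()].
#' @param keys non-empty subset of `email`, `name`, `phone`, `postcode`,
#'   `ip`.
#' @return data frame with `record_id`, `group`, `retain`, ordered by group
#'   then `started_at`; only groups of two or more appear.
#' @export
find_duplicates <- function(dataset, keys = c("email", "phone")) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (!length(keys)) stopf("keys must be non-empty")
  bad <- setdiff(keys, .identifier_fields)
  if (length(bad)) {
    stopf("not identifier fields: %s", paste(bad, collapse = ", "))
  }
  recs <- dataset$records
  n <- nrow(recs)
  if (n == 0) return(data.frame(record_id = character(), group = integer(),
                                retain = logical()))
  parent <- uf_new(n)
  for (k in keys) {
    v <- normalize_key(recs[[k]])
    idx <- which(!is.na(v))
    if (!length(idx)) next
    sp <- split(idx, v[idx])
    for (g in sp) {
      if (length(g) > 1) {
        for (j in g[-1]) parent <- uf_union(parent, g[1], j)
      }
    }
  }
  root <- uf_roots(parent)
  sizes <- table(root)
  keep <- root %in% as.integer(names(sizes)[sizes > 1])
  if (!any(keep)) {
    return(data.frame(record_id = character(), group = integer(),
                      retain = logical()))
  }
  out <- data.frame(record_id = recs$record_id[keep],
                    group = match(root[keep], unique(root[keep])),
                    started_at = recs$started_at[keep],
                    idx = which(keep),
                    stringsAsFactors = FALSE)
  out <- out[order(out$group, out$started_at, out$idx), ]
  out$retain <- !duplicated(out$group)
  rownames(out) <- NULL
  out[, c("record_id", "group", "retain")]
}

#' Flag batch submissions
#'
#' Slides over the time-sorted submissions (within shared-identifier groups
#' when `shared_key` is given) and flags every record belonging to a run of
#' at least `min_count` submissions whose consecutive gaps are each at most
#' `window_s` seconds.
#'
#' @param dataset a [survey_dataset()].
#' @param window_s maximum gap between consecutive submissions, seconds.
#' @param min_count minimum run length (>= 2).
#' @param shared_key optional identifier field the run must share.
#' @return character vector of flagged record ids.
#' @export
batch_flag <- function(dataset, window_s, min_count, shared_key = NULL) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (min_count < 2) stopf("min_count must be >= 2")
  recs <- dataset$records
  flag_run <- function(ids, times) {
    ord <- order(times)
    ids <- ids[ord]; times <- times[ord]
    if (length(ids) < min_count) return(character())
    gaps <- diff(as.numeric(times))
    brk <- c(0, which(gaps > window_s), length(ids))
    out <- character()
    for (s in seq_len(length(brk) - 1)) {
      seg <- (brk[s] + 1):brk[s + 1]
      if (length(seg) >= min_count) out <- c(out, ids[seg])
    }
    out
  }
  ok <- !is.na(recs$submitted_at)
  if (is.null(shared_key)) {
    flag_run(recs$record_id[ok], recs$submitted_at[ok])
  } else {
    if (!shared_key %in% .identifier_fields) {
      stopf("shared_key '%s' is not an identifier field", shared_key)
    }
    v <- normalize_key(recs[[shared_key]])
    ok <- ok & !is.na(v)
    sp <- split(which(ok), v[ok])
    unlist(lapply(sp, function(idx) {
      flag_run(recs$record_id[idx], recs$submitted_at[idx])
    }), use.names = FALSE)
  }
}

#' Assess free-text answers as protective
#'
#' Operationalizes "sensical free-text response": at least `min_fields`
#' free-text fields each carrying at least `min_tokens` tokens with a
#' dictionary-word ratio of at least `dict_ratio`, and not verbatim
#' duplicated in any other record's same field. Fires (returns `TRUE`) when
#' the record's free text looks like genuine prose.
#'
#' @param texts named character vector: one record's free-text answers.
#' @param params overrides for `min_fields` (1), `min_tokens` (5),
#'   `dict_ratio` (0.6).
#' @param corpus optional named list mapping each free-text field to the
#'   full column of texts across the dataset, used for the cross-record
#'   duplication check.
#' @return logical scalar.
#' @export
freetext_protective <- function(texts, params = list(), corpus = NULL) {
  p <- utils::modifyList(list(min_fields = 1, min_tokens = 5,
                              dict_ratio = 0.6), params)
  if (is.null(texts) || !length(texts)) return(FALSE)
  ok <- vapply(seq_along(texts), function(i) {
    txt <- texts[[i]]
    if (is.na(txt) || !nzchar(txt)) return(FALSE)
    toks <- tokenize_words(txt)
    if (length(toks) < p$min_tokens) return(FALSE)
    if (mean(toks %in% .ft_dictionary) < p$dict_ratio) return(FALSE)
    if (!is.null(corpus)) {
      fld <- names(texts)[i]
      col <- corpus[[fld]]
      if (!is.null(col) && sum(col == txt, na.rm = TRUE) > 1) return(FALSE)
    }
    TRUE
  }, logical(1))
  sum(ok) >= p$min_fields
}

#' Bot indicator flags for one record
#'
#' @param record one-row data frame or named list.
#' @param captcha_threshold score below which the CAPTCHA flag fires
#'   (strict; default 0.5). A missing score never fires.
#' @return list with `honeypot_fired` (non-empty honeypot value) and
#'   `captcha_fired`.
#' @export
bot_flags <- function(record, captcha_threshold = 0.5) {
  if (is.data.frame(record)) record <- as.list(record)
  hp <- record$honeypot_value %||% ""
  cs <- record$captcha_score %||% NA_real_
  list(honeypot_fired = !is.na(hp) && nzchar(hp),
       captcha_fired = !is.na(cs) && cs < captcha_threshold)
}

#' Remuneration direction for one record
#'
#' Not asking for remuneration is protective; asking for it alone is
#' neutral, never suspicious.
#'
#' @param record one-row data frame or named list.
#' @return `"protective"` or `"neutral"`.
#' @export
remuneration_flag <- function(record) {
  if (is.data.frame(record)) record <- as.list(record)
  req <- record$remuneration_requested
  if (!is.null(req) && !is.na(req) && !req) "protective" else "neutral"
}

#' Submission-date direction relative to fraud onset
#'
#' Submissions strictly before the onset instant are protective; at or
#' after it, suspicious. With no onset set the criterion is inert.
#'
#' @param record one-row data frame or named list.
#' @param fraud_onset_date onset timestamp or `NULL`.
#' @return `"protective"`, `"suspicious"`, or `"none"`.
#' @export
onset_flag <- function(record, fraud_onset_date) {
  if (is.null(fraud_onset_date)) return("none")
  if (is.data.frame(record)) record <- as.list(record)
  su <- parse_utc(record$submitted_at %||% NA)
  if (is.na(su)) return("none")
  if (su < fraud_onset_date) "protective" else "suspicious"
}

#' Flag repeated screening attempts
#'
#' @param record one-row data frame or named list.
#' @return `TRUE` iff `screening_attempts > 1`.
#' @export
screening_attempts_flag <- function(record) {
  if (is.data.frame(record)) record <- as.list(record)
  sa <- record$screening_attempts
  !is.null(sa) && !is.na(sa) && sa > 1
}

# Evaluator registry: each takes (dataset, params) and returns a logical
# fired vector over records. Dataset-context evaluators (duplicates,
# batches, free-text duplication) see the whole dataset.
.evaluators <- list(
  honeypot = function(ds, p) {
    hp <- ds$records$honeypot_value
    !is.na(hp) & nzchar(hp)
  },
  captcha = function(ds, p) {
    thr <- p$threshold %||% 0.5
    cs <- ds$records$captcha_score
    !is.na(cs) & cs < thr
  },
  completion_time = function(ds, p) {
    completion_time_flag(ds$records$duration_s, p$threshold_s %||% 800)
  },
  email_pattern = function(ds, p) {
    email_pattern_flag(ds$records$email, ds$records$name, p)
  },
  duplicate = function(ds, p) {
    groups <- find_duplicates(ds, p$keys %||% c("email", "phone"))
    ds$records$record_id %in% groups$record_id[!groups$retain]
  },
  batch = function(ds, p) {
    ids <- batch_flag(ds, p$window_s %||% 600, p$min_count %||% 3,
                      p$shared_key)
    ds$records$record_id %in% ids
  },
  consistency = function(ds, p) {
    rules <- p$rules %||% default_consistency_rules()
    validate_rules(rules, ds$schema)
    vapply(seq_len(nrow(ds$records)), function(i) {
      length(consistency_violations(ds$records[i, , drop = FALSE], rules)) > 0
    }, logical(1))
  },
  freetext = function(ds, p) {
    flds <- ds$schema$free_text
    if (!length(flds)) return(rep(FALSE, nrow(ds$records)))
    corpus <- stats::setNames(lapply(flds, function(f) ds$records[[f]]), flds)
    vapply(seq_len(nrow(ds$records)), function(i) {
      texts <- stats::setNames(
        vapply(flds, function(f) as.character(ds$records[[f]][i]),
               character(1)), flds)
      freetext_protective(texts, p, corpus = corpus)
    }, logical(1))
  },
  no_remuneration = function(ds, p) {
    req <- ds$records$remuneration_requested
    !is.na(req) & !req
  },
  pre_onset = function(ds, p) {
    if (is.null(ds$fraud_onset_date)) {
      message("onset criterion inert: dataset has no fraud_onset_date")
      return(rep(FALSE, nrow(ds$records)))
    }
    su <- ds$records$submitted_at
    !is.na(su) & su < ds$fraud_onset_date
  },
  post_onset = function(ds, p) {
    if (is.null(ds$fraud_onset_date)) {
      message("onset criterion inert: dataset has no fraud_onset_date")
      return(rep(FALSE, nrow(ds$records)))
    }
    su <- ds$records$submitted_at
    !is.na(su) & su >= ds$fraud_onset_date
  },
  screening_attempts = function(ds, p) {
    sa <- ds$records$screening_attempts
    !is.na(sa) & sa > 1
  },
  registry_unverified = function(ds, p) {
    rv <- ds$records$registry_verified
    !is.na(rv) & !rv
  },
  straightline = function(ds, p) {
    qs <- p$questions %||% grep("^q_likert", names(ds$records), value = TRUE)
    if (length(qs) < 2) return(rep(FALSE, nrow(ds$records)))
    m <- as.matrix(ds$records[, qs, drop = FALSE])
    apply(m, 1, function(r) !anyNA(r) && length(unique(r)) == 1)
  }
)

#' Evaluate a criteria registry over a dataset
#'
#' Produces one result per (record, criterion). Dataset-context evaluators
#' (duplicates, batches, free-text duplication) are computed once over the
#' dataset and broadcast to records. Every evaluator is a pure function of
#' the record, the dataset context, and its parameters.
#'
#' @param dataset a [survey_dataset()].
#' @param registry non-empty list of [criterion()] objects.
#' @return an object of class `criterion_results`: list with `fired`
#'   (record x criterion logical matrix), `points` (signed numeric matrix,
#'   `points[i, j] == registry[[j]]$points` iff fired, else 0), and `specs`.
#' @export
evaluate_criteria <- function(dataset, registry) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (!length(registry)) stopf("criteria registry must be non-empty")
  for (cr in registry) {
    if (!inherits(cr, "fraud_criterion")) {
      stopf("registry entries must be fraud_criterion objects")
    }
  }
  nms <- vapply(registry, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stopf("duplicate criterion names in registry")
  n <- nrow(dataset$records)
  fired <- matrix(FALSE, n, length(registry),
                  dimnames = list(dataset$records$record_id, nms))
  pts <- numeric(length(registry))
  for (j in seq_along(registry)) {
    cr <- registry[[j]]
    fired[, j] <- .evaluators[[cr$evaluator]](dataset, cr$params)
    pts[j] <- cr$points
  }
  points <- sweep(fired, 2, pts, `*`)
  structure(list(fired = fired, points = points, specs = registry),
            class = "criterion_results")
}

#' @export
print.criterion_results <- function(x, ...) {
  cat(sprintf("criterion_results: %d records x %d criteria\n",
              nrow(x$fired), ncol(x$fired)))
  rates <- round(100 * colMeans(x$fired), 1)
  for (j in seq_len(ncol(x$fired))) {
    cat(sprintf("  %-22s %+g pts, fired %5.1f%%\n",
                colnames(x$fired)[j], x$specs[[j]]$points, rates[j]))
  }
  invisible(x)
}

#' Shipped criteria presets
#'
#' Registries encoding each case study's described criteria and thresholds:
#' `case1` is the full signed-point algorithm for an anonymized long survey
#' (protective free text, no-remuneration, pre-onset submission; suspicious
#' nonsensical combinations, honeypot, low CAPTCHA, fast completion at
#' 800 s, pattern emails, duplicates, batches, repeated screening);
#' `case2` the verification-oriented short-survey set (300 s minimum,
#' same-account batches); `case3` the identifier-rich set (800 s screen,
#' duplicates on name/phone/email/IP, platform flags); `case4` the
#' screening-signal set.
#'
#' @param name one of `"case1"`, `"case2"`, `"case3"`, `"case4"`.
#' @return list of [criterion()] objects.
#' @export
criteria_preset <- function(name = c("case1", "case2", "case3", "case4")) {
  name <- match.arg(name)
  switch(name,
    case1 = list(
      criterion("freetext_sensical", "protective", -3, "freetext"),
      criterion("no_remuneration", "protective", -1, "no_remuneration"),
      criterion("pre_onset", "protective", -2, "pre_onset"),
      criterion("nonsense_combo", "suspicious", 3, "consistency"),
      criterion("post_onset", "suspicious", 1, "post_onset"),
      criterion("honeypot", "suspicious", 4, "honeypot"),
      criterion("captcha_low", "suspicious", 2, "captcha",
                list(threshold = 0.5)),
      criterion("fast_completion", "suspicious", 2, "completion_time",
                list(threshold_s = 800)),
      criterion("email_pattern", "suspicious", 3, "email_pattern"),
      criterion("duplicate_entry", "suspicious", 2, "duplicate",
                list(keys = c("email", "phone"))),
      criterion("batch_submission", "suspicious", 2, "batch",
                list(window_s = 600, min_count = 3, shared_key = "ip")),
      criterion("multiple_screening", "suspicious", 2, "screening_attempts")),
    case2 = list(
      criterion("fast_completion", "suspicious", 3, "completion_time",
                list(threshold_s = 300)),
      criterion("email_pattern", "suspicious", 3, "email_pattern"),
      criterion("honeypot", "suspicious", 4, "honeypot"),
      criterion("captcha_low", "suspicious", 2, "captcha"),
      criterion("batch_submission", "suspicious", 3, "batch",
                list(window_s = 1200, min_count = 3, shared_key = "email")),
      criterion("duplicate_entry", "suspicious", 2, "duplicate"),
      criterion("registry_unverified", "suspicious", 3,
                "registry_unverified"),
      criterion("freetext_sensical", "protective", -2, "freetext")),
    case3 = list(
      criterion("fast_completion", "suspicious", 3, "completion_time",
                list(threshold_s = 800)),
      criterion("duplicate_entry", "suspicious", 3, "duplicate",
                list(keys = c("name", "phone", "email", "ip"))),
      criterion("captcha_low", "suspicious", 3, "captcha"),
      criterion("batch_submission", "suspicious", 2, "batch",
                list(window_s = 600, min_count = 3, shared_key = "ip")),
      criterion("freetext_sensical", "protective", -2, "freetext")),
    case4 = list(
      criterion("multiple_screening", "suspicious", 3, "screening_attempts"),
      criterion("nonsense_combo", "suspicious", 3, "consistency"),
      criterion("straightline", "suspicious", 2, "straightline"),
      criterion("honeypot", "suspicious", 4, "honeypot"),
      criterion("captcha_low", "suspicious", 2, "captcha"),
      criterion("freetext_sensical", "protective", -2, "freetext"))
  )
}

#' Read a criteria registry (and optional consistency rules) from YAML
#'
#' The file holds a `criteria` sequence of maps (`name`, `direction`,
#' `points`, `evaluator`, optional `params`) and an optional `rules`
#' sequence (`name`, `clauses`).
#'
#' @param path YAML file path.
#' @return list with elements `criteria` and `rules`.
#' @export
read_criteria_yaml <- function(path) {
  if (!file.exists(path)) stopf("criteria file not found: %s", path)
  y <- yaml::read_yaml(path)
  rules <- lapply(y$rules %||% list(), function(r) {
    consistency_rule(r$name, r$clauses)
  })
  crits <- lapply(y$criteria %||% list(), function(cr) {
    params <- cr$params %||% list()
    if (identical(cr$evaluator, "consistency") && length(rules) &&
        is.null(params$rules)) {
      params$rules <- rules
    }
    criterion(cr$name, cr$direction, cr$points, cr$evaluator, params)
  })
  if (!length(crits)) stopf("config error: no criteria in %s", path)
  list(criteria = crits, rules = rules)
}
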