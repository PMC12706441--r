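# Data model: respondent records, dataset container, schema declaration,
# and flat-file I/O (CSV or JSON-lines; YAML for the schema).

.std_cols <- c("record_id", "started_at", "submitted_at", "duration_s",
               "email", "name", "phone", "postcode", "ip",
               "remuneration_requested", "captcha_score", "honeypot_value",
               "screening_attempts", "registry_verified", "truth_archetype")

.identifier_fields <- c("email", "name", "phone", "postcode", "ip")

.archetypes <- c("genuine", "duplicator", "misrepresenter", "bot")

#' Declare a survey schema
#'
#' A schema names the substantive question columns of a survey export and
#' their value domains, plus which columns hold free-text answers. Screening
#' operations only ever touch declared questions, the free-text fields, and
#' the standard respondent metadata (identifiers, timestamps, platform
#' flags), so undeclared columns in an export are ignored rather than
#' misread.
#'
#' @param questions named list; each element is either a character vector of
#'   admissible categorical levels, or the string `"numeric"` or `"text"`
#'   for unconstrained numeric/text questions.
#' @param free_text character vector of question ids whose values are
#'   free-text answers (these are checked by the free-text plausibility
#'   criterion, not against a domain).
#' @return an object of class `survey_schema`.
#' @seealso [read_survey_schema()] to load a schema from YAML,
#'   [survey_dataset()] for the container that pairs records with a schema.
#' @export
survey_schema <- function(questions = list(), free_text = character()) {
  if (length(questions) && is.null(names(questions))) {
    stopf("`questions` must be a named list of question ids")
  }
  free_text <- as.character(free_text)
  if (any(free_text %in% names(questions))) {
    stopf("free-text ids must not also be declared as domain questions")
  }
  structure(list(questions = questions, free_text = free_text),
            class = "survey_schema")
}

#' Read a survey schema from a YAML file
#'
#' The file holds a `questions` map (question id to a list of levels or the
#' word `numeric`/`text`) and an optional `free_text` sequence.
#'
#' @param path path to a YAML file.
#' @return a [survey_schema()] object.
#' @export
read_survey_schema <- function(path) {
  if (!file.exists(path)) stopf("schema file not found: %s", path)
  y <- yaml::read_yaml(path)
  qs <- lapply(y$questions %||% list(), function(d) {
    if (length(d) == 1 && d %in% c("numeric", "text")) as.character(d)
    else as.character(unlist(d))
  })
  survey_schema(questions = qs, free_text = y$free_text %||% character())
}

question_ids <- function(schema) {
  c(names(schema$questions), schema$free_text)
}

# Blank one-row records frame with all standard columns, used to fill in
# whatever an export did not supply.
empty_records <- function(n) {
  data.frame(
    record_id = rep(NA_character_, n),
    started_at = as.POSIXct(rep(NA_real_, n), origin = "1970-01-01", tz = "UTC"),
    submitted_at = as.POSIXct(rep(NA_real_, n), origin = "1970-01-01", tz = "UTC"),
    duration_s = rep(NA_real_, n),
    email = rep(NA_character_, n),
    name = rep(NA_character_, n),
    phone = rep(NA_character_, n),
    postcode = rep(NA_character_, n),
    ip = rep(NA_character_, n),
    remuneration_requested = rep(NA, n),
    captcha_score = rep(NA_real_, n),
    honeypot_value = rep("", n),
    screening_attempts = rep(1L, n),
    registry_verified = rep(NA, n),
    truth_archetype = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
}

#' Construct a survey dataset
#'
#' Bundles a records data frame with its schema and the optional fraud-onset
#' timestamp (the instant at which in-flight monitoring first detected
#' suspicious activity; submissions before it count as protective evidence).
#'
#' Record ids must be unique. Where both timestamps are present the stored
#' duration is recomputed from them; the stored value is used otherwise.
#'
#' @param records data frame with at least a `record_id` column; standard
#'   respondent columns (timestamps, identifiers, platform flags) are added
#'   as missing when absent, and declared question columns are kept.
#' @param schema a [survey_schema()].
#' @param fraud_onset_date optional timestamp (parseable as UTC) marking
#'   detected fraud onset; must lie within the dataset's submission window
#'   extended by one day.
#' @return an object of class `survey_dataset`: a list with elements
#'   `records`, `schema`, `fraud_onset_date`.
#' @export
survey_dataset <- function(records, schema = survey_schema(),
                           fraud_onset_date = NULL) {
  stopifnot(is.data.frame(records))
  if (!"record_id" %in% names(records)) {
    stopf("schema error: records have no `record_id` column")
  }
  n <- nrow(records)
  out <- empty_records(n)
  for (col in .std_cols) {
    if (col %in% names(records)) {
      v <- records[[col]]
      if (col %in% c("started_at", "submitted_at")) v <- parse_utc(v)
      if (col %in% c("duration_s", "captcha_score")) v <- as.numeric(v)
      if (col == "screening_attempts") v <- as.integer(v)
      if (col %in% c("remuneration_requested", "registry_verified")) v <- as.logical(v)
      if (col == "honeypot_value") {
        v <- as.character(v)
        v[is.na(v)] <- ""
      }
      if (col %in% c("record_id", "email", "name", "phone", "postcode", "ip",
                     "truth_archetype")) v <- as.character(v)
      out[[col]] <- v
    }
  }
  dup <- unique(out$record_id[duplicated(out$record_id)])
  if (length(dup)) {
    stopf("load error: duplicate record_id values: %s",
          paste(dup, collapse = ", "))
  }
  both <- !is.na(out$started_at) & !is.na(out$submitted_at)
  out$duration_s[both] <- as.numeric(difftime(out$submitted_at[both],
                                              out$started_at[both],
                                              units = "secs"))
  for (q in question_ids(schema)) {
    if (q %in% names(records)) {
      v <- records[[q]]
      dom <- schema$questions[[q]]
      if (!is.null(dom) && identical(dom, "numeric")) v <- as.numeric(v)
      else v <- as.character(v)
      out[[q]] <- v
    } else {
      dom <- schema$questions[[q]]
      out[[q]] <- if (!is.null(dom) && identical(dom, "numeric")) {
        rep(NA_real_, n)
      } else if (q %in% schema$free_text) rep("", n) else rep(NA_character_, n)
    }
  }
  ds <- structure(list(records = out, schema = schema,
                       fraud_onset_date = NULL),
                  class = "survey_dataset")
  if (!is.null(fraud_onset_date)) {
    onset <- parse_utc(fraud_onset_date)
    if (is.na(onset)) stopf("fraud_onset_date could not be parsed")
    if (n > 0 && any(!is.na(out$started_at))) {
      lo <- min(out$started_at, na.rm = TRUE)
      hi <- max(out$submitted_at, na.rm = TRUE) + 86400
      if (onset < lo || onset > hi) {
        stopf("fraud_onset_date outside the dataset window [%s, %s]",
              format_utc(lo), format_utc(hi))
      }
    }
    ds$fraud_onset_date <- onset
  }
  ds
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf("survey_dataset: %d records, %d declared questions\n",
              nrow(x$records), length(question_ids(x$schema))))
  if (!is.null(x$fraud_onset_date)) {
    cat(sprintf("  fraud onset: %s\n", format_utc(x$fraud_onset_date)))
  }
  if (any(!is.na(x$records$truth_archetype))) {
    tab <- table(x$records$truth_archetype)
    cat("  truth labels:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Validate a single respondent record
#'
#' Checks the record-level invariants: non-negative duration, duration
#' consistent with the two timestamps when both are present, CAPTCHA score
#' inside \[0,1\], non-negative screening attempts, submission not before
#' start, and every declared categorical answer inside its domain.
#' Violations are data, not errors.
#'
#' @param record a one-row data frame or a named list with record fields.
#' @param schema a [survey_schema()].
#' @return data frame with columns `field`, `rule`, `message`; zero rows iff
#'   the record is valid.
#' @export
validate_record <- function(record, schema = survey_schema()) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1)
    record <- as.list(record)
  }
  v <- list()
  add <- function(field, rule, message) {
    v[[length(v) + 1]] <<- data.frame(field = field, rule = rule,
                                      message = message,
                                      stringsAsFactors = FALSE)
  }
  dur <- record$duration_s
  if (!is.null(dur) && !is.na(dur) && dur < 0) {
    add("duration_s", "non_negative", "duration_s is negative")
  }
  st <- parse_utc(record$started_at %||% NA)
  su <- parse_utc(record$submitted_at %||% NA)
  if (!is.na(st) && !is.na(su)) {
    if (su < st) add("submitted_at", "ordered_timestamps",
                     "submitted_at precedes started_at")
    if (!is.null(dur) && !is.na(dur) &&
        abs(as.numeric(difftime(su, st, units = "secs")) - dur) > 1) {
      add("duration_s", "duration_consistent",
          "duration_s does not match submitted_at - started_at")
    }
  }
  cs <- record$captcha_score
  if (!is.null(cs) && !is.na(cs) && (cs < 0 || cs > 1)) {
    add("captcha_score", "unit_interval", "captcha_score outside [0, 1]")
  }
  sa <- record$screening_attempts
  if (!is.null(sa) && !is.na(sa) && sa < 0) {
    add("screening_attempts", "non_negative", "screening_attempts is negative")
  }
  ta <- record$truth_archetype
  if (!is.null(ta) && !is.na(ta) && !(ta %in% .archetypes)) {
    add("truth_archetype", "domain",
        sprintf("unknown archetype '%s'", ta))
  }
  for (q in names(schema$questions)) {
    dom <- schema$questions[[q]]
    val <- record[[q]]
    if (is.null(val) || length(val) == 0 || is.na(val)) next
    if (identical(dom, "numeric")) {
      if (!is.numeric(val) && is.na(suppressWarnings(as.numeric(val)))) {
        add(q, "domain", sprintf("answer '%s' is not numeric", val))
      }
    } else if (!identical(dom, "text")) {
      if (!(as.character(val) %in% dom)) {
        add(q, "domain", sprintf("answer '%s' not in declared domain", val))
      }
    }
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(field = character(), rule = character(), message = character(),
               stringsAsFactors = FALSE)
}

#' Validate every record of a dataset
#'
#' @param dataset a [survey_dataset()].
#' @return data frame with columns `record_id`, `field`, `rule`, `message`.
#' @export
validate_records <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  recs <- dataset$records
  out <- lapply(seq_len(nrow(recs)), function(i) {
    vi <- validate_record(recs[i, , drop = FALSE], dataset$schema)
    if (nrow(vi)) cbind(record_id = recs$record_id[i], vi) else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out)) do.call(rbind, out) else
    data.frame(record_id = character(), field = character(),
               rule = character(), message = character(),
               stringsAsFactors = FALSE)
}

#' Load survey responses from a flat file
#'
#' Reads a CSV (comma-delimited, quoted text, UTF-8) or JSON-lines export
#' into a [survey_dataset()]. Rows that cannot be parsed are collected into
#' a rejects report attached as `attr(x, "rejects")`, never silently
#' dropped. A missing `record_id` column is a schema error; duplicated ids
#' are a load error naming the ids.
#'
#' @param path file path; `.jsonl`/`.ndjson`/`.json` are read as JSON-lines,
#'   anything else as CSV.
#' @param schema a [survey_schema()] declaring the question columns.
#' @param fraud_onset_date optional onset timestamp to set on the dataset.
#' @return a `survey_dataset`; inspect `attr(x, "rejects")` for rejected rows.
#' @export
load_responses <- function(path, schema = survey_schema(),
                           fraud_onset_date = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  rejects <- data.frame(row = integer(), reason = character(),
                        stringsAsFactors = FALSE)
  if (grepl("\\.(jsonl|ndjson|json)$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    parsed <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      parsed[[i]] <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) e)
      if (inherits(parsed[[i]], "error")) {
        rejects <- rbind(rejects, data.frame(
          row = i, reason = conditionMessage(parsed[[i]])))
        parsed[[i]] <- NULL
      }
    }
    parsed <- parsed[!vapply(parsed, is.null, logical(1))]
    if (!length(parsed)) stopf("no parseable records in %s", path)
    cols <- unique(unlist(lapply(parsed, names)))
    raw <- as.data.frame(
      lapply(cols, function(cn) {
        vapply(parsed, function(p) {
          v <- p[[cn]]
          if (is.null(v) || length(v) == 0) NA_character_ else as.character(v)[1]
        }, character(1))
      }), stringsAsFactors = FALSE)
    names(raw) <- cols
  } else {
    raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                           na.strings = "NA", fileEncoding = "UTF-8")
  }
  if (!"record_id" %in% names(raw)) {
    stopf("schema error: %s has no `record_id` column", path)
  }
  bad_id <- is.na(raw$record_id) | !nzchar(trimws(raw$record_id))
  bad_ts <- rep(FALSE, nrow(raw))
  for (col in c("started_at", "submitted_at")) {
    if (col %in% names(raw)) {
      given <- !is.na(raw[[col]]) & nzchar(raw[[col]])
      bad_ts <- bad_ts | (given & is.na(parse_utc(raw[[col]])))
    }
  }
  drop <- bad_id | bad_ts
  if (any(drop)) {
    rejects <- rbind(rejects, data.frame(
      row = which(drop),
      reason = ifelse(bad_id[drop], "missing record_id", "unparseable timestamp")))
    raw <- raw[!drop, , drop = FALSE]
  }
  ds <- survey_dataset(raw, schema = schema, fraud_onset_date = fraud_onset_date)
  attr(ds, "rejects") <- rejects
  ds
}

#' Write survey responses to a flat file
#'
#' Inverse of [load_responses()]: standard columns, then declared question
#' columns, with ISO-8601 UTC timestamps. By default the synthetic truth
#' label column is withheld so that screening inputs stay blinded; use
#' [write_truth()] for the sidecar.
#'
#' @param dataset a [survey_dataset()].
#' @param path output path; `.jsonl` writes JSON-lines, otherwise CSV.
#' @param include_truth keep the `truth_archetype` column (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_responses <- function(dataset, path, include_truth = FALSE) {
  stopifnot(inherits(dataset, "survey_dataset"))
  recs <- dataset$records
  recs$started_at <- format_utc(recs$started_at)
  recs$submitted_at <- format_utc(recs$submitted_at)
  if (!include_truth) recs$truth_archetype <- NULL
  if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(recs))) {
      row <- as.list(recs[i, , drop = FALSE])
      row <- row[!vapply(row, function(v) is.na(v) || is.null(v), logical(1))]
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, null = "null",
                                  digits = NA), con)
    }
  } else {
    utils::write.csv(recs, path, row.names = FALSE, na = "NA",
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Write the synthetic truth-label sidecar
#'
#' Emits `record_id`, `truth_archetype` and, when the dataset carries them,
#' the generator's latent free-text plausibility labels. Kept separate from
#' the screening inputs so the pipeline never sees ground truth.
#'
#' @param dataset a [survey_dataset()] produced by [generate_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(dataset, path) {
  stopifnot(inherits(dataset, "survey_dataset"))
  out <- dataset$records[, c("record_id", "truth_archetype"), drop = FALSE]
  lat <- attr(dataset, "latent")
  if (!is.null(lat)) out <- merge(out, lat, by = "record_id", sort = FALSE)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write per-respondent score decisions
#'
#' Emits one row per record: id, total fraud score, bucket, final decision,
#' and the fired criteria (semicolon-joined). Errors if any decision names a
#' record absent from the dataset, or any record lacks a decision.
#'
#' @param dataset a [survey_dataset()].
#' @param decisions data frame as returned in the `decisions` element of a
#'   [fraud_screen()] fit (columns `record_id`, `total_score`, `bucket`,
#'   `final`, `fired_criteria`, `review_reason`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @seealso [read_decisions()]
#' @export
write_decisions <- function(dataset, decisions, path) {
  stopifnot(inherits(dataset, "survey_dataset"), is.data.frame(decisions))
  ids <- dataset$records$record_id
  unknown <- setdiff(decisions$record_id, ids)
  if (length(unknown)) {
    stopf("decisions name unknown record_id: %s", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(ids, decisions$record_id)
  if (length(missing)) {
    stopf("no decision for record_id: %s", paste(missing, collapse = ", "))
  }
  cols <- c("record_id", "total_score", "bucket", "final",
            "fired_criteria", "review_reason")
  for (cn in setdiff(cols, names(decisions))) decisions[[cn]] <- NA_character_
  utils::write.csv(decisions[, cols], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a decisions table written by [write_decisions()]
#'
#' @param path CSV path.
#' @return data frame with the decision columns.
#' @export
read_decisions <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  out$record_id <- as.character(out$record_id)
  out
}
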