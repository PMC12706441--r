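# Synthetic respondent cohorts. The generator emulates the fraud phenomena
# the screening pipeline targets -- duplicate entries sharing identifiers,
# bot waves submitted minutes apart after a fraud-onset date, misrepresenting
# humans with internally inconsistent answers, and genuine respondents with
# name-concordant emails and plausible free text -- with every rate
# configurable and every record carrying its ground-truth archetype.

.prob_fields <- c("email_concordance_prob", "freetext_plausibility_prob",
                  "honeypot_prob", "inconsistent_answer_prob",
                  "remuneration_request_prob", "multi_attempt_prob",
                  "post_onset_prob", "straightline_prob")

#' Configure a synthetic respondent cohort
#'
#' All rates are per-archetype named vectors over
#' `genuine`, `duplicator`, `misrepresenter`, `bot`. Durations are
#' log-normal for humans (parameterized by median seconds and log-sd) and
#' uniform for bots; `post_onset_prob` gives the probability that an
#' archetype's submission falls after the fraud-onset instant (`NA` means
#' uniform over the whole recruitment window, as for genuine respondents).
#'
#' @param n_records number of response records to generate.
#' @param prevalence named non-negative fractions over the four archetypes,
#'   summing to 1.
#' @param window_start,window_days recruitment window (UTC start, length in
#'   days).
#' @param fraud_onset_fraction position of the fraud-onset instant within
#'   the window, in \[0,1\].
#' @param batch bot submission waves: list with `n_waves`, `wave_size`
#'   (at least 2) and `window_s` (maximum gap between consecutive wave
#'   submissions, seconds). Wave members share an IP address.
#' @param genuine_duration,misrepresenter_duration list(median_s, sigma)
#'   log-normal completion-time parameters.
#' @param bot_duration length-2 uniform bounds in seconds.
#' @param email_concordance_prob probability the email local part is built
#'   from the respondent's name.
#' @param freetext_plausibility_prob probability the latent free-text
#'   plausibility label is TRUE (plausible dictionary-word sentences are
#'   then generated; otherwise empty, repeated-token, or garbage text).
#' @param honeypot_prob probability of a non-empty honeypot value.
#' @param inconsistent_answer_prob probability of an internally
#'   inconsistent demographic answer combination.
#' @param remuneration_request_prob probability of requesting remuneration.
#' @param multi_attempt_prob probability of more than one screening attempt.
#' @param captcha_beta per-archetype `c(alpha, beta)` Beta parameters for
#'   the platform CAPTCHA score.
#' @param captcha_missing_prob probability the platform reported no score.
#' @param duplicate_multiplicity integer range `c(lo, hi)` of entries per
#'   duplicator identity group.
#' @param straightline_prob probability all Likert answers are identical.
#' @param trusted_domain_prob probability a concordant email uses a known
#'   institutional domain (these become negative-control candidates).
#' @param seed integer seed; generation is a pure function of the config.
#' @return an object of class `cohort_config`.
#' @seealso [cohort_preset()] for study-shaped presets, [generate_cohort()].
#' @export
cohort_config <- function(n_records = 1000,
                          prevalence = c(genuine = 0.55, duplicator = 0.05,
                                         misrepresenter = 0.10, bot = 0.30),
                          window_start = "2020-07-01", window_days = 183,
                          fraud_onset_fraction = 0.53,
                          batch = list(n_waves = 4, wave_size = 25,
                                       window_s = 300),
                          genuine_duration = list(median_s = 900, sigma = 0.5),
                          misrepresenter_duration = list(median_s = 700,
                                                         sigma = 0.4),
                          bot_duration = c(30, 300),
                          email_concordance_prob = c(genuine = 0.95,
                                                     duplicator = 0.90,
                                                     misrepresenter = 0.30,
                                                     bot = 0.02),
                          freetext_plausibility_prob = c(genuine = 0.95,
                                                         duplicator = 0.90,
                                                         misrepresenter = 0.20,
                                                         bot = 0.05),
                          honeypot_prob = c(genuine = 0, duplicator = 0,
                                            misrepresenter = 0, bot = 0.90),
                          inconsistent_answer_prob = c(genuine = 0.01,
                                                       duplicator = 0.01,
                                                       misrepresenter = 0.90,
                                                       bot = 0.50),
                          remuneration_request_prob = c(genuine = 0.80,
                                                        duplicator = 1,
                                                        misrepresenter = 1,
                                                        bot = 1),
                          multi_attempt_prob = c(genuine = 0.02,
                                                 duplicator = 0.10,
                                                 misrepresenter = 0.30,
                                                 bot = 0.40),
                          captcha_beta = list(genuine = c(8, 2),
                                              duplicator = c(8, 2),
                                              misrepresenter = c(6, 3),
                                              bot = c(2, 8)),
                          captcha_missing_prob = 0.10,
                          duplicate_multiplicity = c(2, 4),
                          straightline_prob = c(genuine = 0.05,
                                                duplicator = 0.05,
                                                misrepresenter = 0.20,
                                                bot = 0.80),
                          post_onset_prob = c(genuine = NA, duplicator = NA,
                                              misrepresenter = 0.80,
                                              bot = 0.95),
                          trusted_domain_prob = 0.35,
                          seed = 1L) {
  cfg <- as.list(environment())
  if (!is.numeric(n_records) || n_records < 1) {
    stopf("config error: n_records must be a positive integer")
  }
  cfg$n_records <- as.integer(n_records)
  prev <- prevalence[.archetypes]
  prev[is.na(prev)] <- 0
  names(prev) <- .archetypes
  if (any(prev < 0)) stopf("config error: prevalence fractions must be non-negative")
  if (abs(sum(prev) - 1) > 1e-9) {
    stopf("config error: prevalence fractions sum to %.6f, not 1", sum(prev))
  }
  cfg$prevalence <- prev
  for (f in .prob_fields) {
    v <- cfg[[f]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stopf("config error: %s must lie in [0, 1]", f)
    }
  }
  if (cfg$fraud_onset_fraction < 0 || cfg$fraud_onset_fraction > 1) {
    stopf("config error: fraud_onset_fraction must lie in [0, 1]")
  }
  if (!is.null(batch) && batch$wave_size < 2) {
    stopf("config error: batch wave_size must be >= 2")
  }
  if (cfg$duplicate_multiplicity[1] < 2) {
    stopf("config error: duplicate multiplicity must be >= 2")
  }
  structure(cfg, class = "cohort_config")
}

#' Study-shaped cohort presets
#'
#' Named parameter sets emulating the broad shape of the four survey case
#' studies the package's screening rules come from: a long anonymized
#' clinician survey with roughly 45% fraudulent records and a mid-window
#' fraud onset (`case1_like`); a shorter clinician survey hit early by large
#' same-account batch waves (`case2_like`); a patient survey with mostly
#' genuine respondents and an 800-second completion-time screen
#' (`case3_like`). These are stated modelling assumptions, not published
#' generative parameters.
#'
#' `case1_like_separable` keeps the `case1_like` shape but makes the
#' archetype signals fully separable -- bots always trip the honeypot and
#' genuine respondents never do, email concordance and free-text
#' plausibility are 1 for genuine and 0 for fraudulent archetypes, and
#' misrepresenters always carry an inconsistent answer combination. It is
#' the configuration under which pipeline recovery of the truth labels is
#' validated.
#'
#' @param name one of `"case1_like"`, `"case1_like_separable"`,
#'   `"case2_like"`, `"case3_like"`.
#' @param ... overrides passed to [cohort_config()].
#' @return a `cohort_config`.
#' @export
cohort_preset <- function(name = c("case1_like", "case1_like_separable",
                                   "case2_like", "case3_like"),
                          ...) {
  name <- match.arg(name)
  over <- list(...)
  base <- switch(name,
    case1_like = list(),
    case1_like_separable = list(
      email_concordance_prob = c(genuine = 1, duplicator = 1,
                                 misrepresenter = 0, bot = 0),
      freetext_plausibility_prob = c(genuine = 1, duplicator = 1,
                                     misrepresenter = 0, bot = 0),
      honeypot_prob = c(genuine = 0, duplicator = 0, misrepresenter = 0,
                        bot = 1),
      inconsistent_answer_prob = c(genuine = 0, duplicator = 0,
                                   misrepresenter = 1, bot = 1),
      multi_attempt_prob = c(genuine = 0, duplicator = 0.10,
                             misrepresenter = 0.5, bot = 0.5),
      captcha_beta = list(genuine = c(12, 2), duplicator = c(12, 2),
                          misrepresenter = c(2, 8), bot = c(1, 12))),
    case2_like = list(
      window_start = "2021-07-19", window_days = 180,
      fraud_onset_fraction = 0.08,
      prevalence = c(genuine = 0.30, duplicator = 0.05,
                     misrepresenter = 0.15, bot = 0.50),
      genuine_duration = list(median_s = 720, sigma = 0.4),
      batch = list(n_waves = 4, wave_size = 75, window_s = 1200)),
    case3_like = list(
      window_start = "2023-02-01", window_days = 90,
      fraud_onset_fraction = 0.15,
      prevalence = c(genuine = 0.84, duplicator = 0.06,
                     misrepresenter = 0.04, bot = 0.06),
      genuine_duration = list(median_s = 1100, sigma = 0.4))
  )
  do.call(cohort_config, utils::modifyList(base, over))
}

# Default schema shared by the generator and the shipped criteria presets:
# two linked demographic questions that admit nonsensical combinations,
# years in practice, three Likert items, and one free-text field.
default_schema <- function() {
  survey_schema(
    questions = list(
      specialty = c("family_medicine", "obgyn", "mfm_subspecialist",
                    "nurse_practitioner"),
      college = c("CFPC", "RCPSC", "CNA", "none"),
      years_practice = "numeric",
      q_likert1 = "numeric", q_likert2 = "numeric", q_likert3 = "numeric"),
    free_text = "ft_other_services")
}

r_sentence <- function(n_words) {
  w <- sample(.ft_dictionary, n_words, replace = TRUE)
  w[1] <- paste0(toupper(substring(w[1], 1, 1)), substring(w[1], 2))
  paste(w, collapse = " ")
}

r_garbage_text <- function() {
  kind <- sample(c("empty", "repeat", "garbage"), 1,
                 prob = c(0.3, 0.3, 0.4))
  if (kind == "empty") return("")
  if (kind == "repeat") {
    w <- sample(.ft_dictionary, 1)
    return(paste(rep(w, sample(3:4, 1)), collapse = " "))
  }
  paste(vapply(seq_len(sample(4:8, 1)), function(i) {
    paste(sample(strsplit("bcdfghjklmnpqrstvwxz", "")[[1]],
                 sample(4:7, 1), replace = TRUE), collapse = "")
  }, character(1)), collapse = " ")
}

r_concordant_email <- function(first, last, trusted_p) {
  style <- sample(c("dot", "initial"), 1)
  local <- if (style == "dot") paste0(first, ".", last)
           else paste0(substring(first, 1, 1), last)
  if (stats::runif(1) < 0.8) {
    local <- paste0(local, paste(sample(0:9, sample(1:4, 1), replace = TRUE),
                                 collapse = ""))
  }
  dom <- if (stats::runif(1) < trusted_p) sample(.trusted_domains, 1)
         else sample(.generic_domains, 1)
  paste0(local, "@", dom)
}

# Alternating letter/digit-block locals ("qw12er34ty56") or digit-only
# locals -- the email shapes the control-designation rules treat as
# suspicious by default.
r_pattern_email <- function() {
  if (stats::runif(1) < 0.3) {
    local <- paste(sample(0:9, sample(8:12, 1), replace = TRUE), collapse = "")
  } else {
    k <- sample(3:5, 1)
    blocks <- vapply(seq_len(k), function(i) {
      paste0(paste(sample(letters, sample(1:2, 1), replace = TRUE),
                   collapse = ""),
             paste(sample(0:9, sample(1:2, 1), replace = TRUE),
                   collapse = ""))
    }, character(1))
    local <- paste(blocks, collapse = "")
  }
  paste0(local, "@", sample(c(.suspicious_domains, .generic_domains), 1))
}

r_alias_email <- function() {
  w <- sample(.ft_dictionary[nchar(.ft_dictionary) >= 4], 1)
  paste0(w, paste(sample(0:9, 2, replace = TRUE), collapse = ""),
         "@", sample(.generic_domains, 1))
}

r_phone <- function(n) {
  vapply(seq_len(n), function(i) {
    paste0("04", paste(sample(0:9, 8, replace = TRUE), collapse = ""))
  }, character(1))
}

r_ip <- function(n) {
  paste(sample(11:220, n, replace = TRUE), sample(0:255, n, replace = TRUE),
        sample(0:255, n, replace = TRUE), sample(1:254, n, replace = TRUE),
        sep = ".")
}

#' Generate a labelled synthetic survey dataset
#'
#' A pure function of its config: identical configs (including the seed)
#' yield byte-identical datasets. Duplicator records share an email, phone,
#' and name within their multiplicity groups; bots concentrate after the
#' fraud-onset instant, trip the honeypot at the configured rate, draw short
#' uniform durations, and partly arrive in submission waves sharing an IP;
#' misrepresenters carry nonsensical demographic answer combinations at the
#' configured rate; genuine respondents draw plausible dictionary-word free
#' text and name-concordant emails.
#'
#' The generator's latent free-text plausibility labels are attached as
#' `attr(x, "latent")` so the free-text criterion can be validated against
#' them, and `truth_archetype` is set on every record.
#'
#' @param config a [cohort_config()].
#' @return a [survey_dataset()] with `fraud_onset_date` set.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, as.list(config))
  }
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_records
  arch <- sample(.archetypes, n, replace = TRUE, prob = cfg$prevalence)
  w0 <- parse_utc(cfg$window_start)
  w1 <- w0 + cfg$window_days * 86400
  onset <- w0 + cfg$fraud_onset_fraction * cfg$window_days * 86400

  p_of <- function(field) {
    v <- unname(cfg[[field]][arch])
    v[is.na(v)] <- 0
    v
  }

  first <- sample(.first_names, n, replace = TRUE)
  last <- sample(.last_names, n, replace = TRUE)
  phone <- r_phone(n)
  ip <- r_ip(n)
  postcode <- sprintf("%04d", sample(800:7999, n, replace = TRUE))

  # duration by archetype
  dur <- numeric(n)
  for (a in c("genuine", "duplicator")) {
    idx <- which(arch == a)
    dur[idx] <- stats::rlnorm(length(idx),
                              log(cfg$genuine_duration$median_s),
                              cfg$genuine_duration$sigma)
  }
  idx <- which(arch == "misrepresenter")
  dur[idx] <- stats::rlnorm(length(idx),
                            log(cfg$misrepresenter_duration$median_s),
                            cfg$misrepresenter_duration$sigma)
  idx <- which(arch == "bot")
  dur[idx] <- stats::runif(length(idx), cfg$bot_duration[1],
                           cfg$bot_duration[2])
  dur <- round(dur)

  # submission instants: uniform over the window unless the archetype is
  # onset-concentrated
  submitted <- w0 + stats::runif(n, 0, as.numeric(difftime(w1, w0, units = "secs")))
  for (a in c("misrepresenter", "bot")) {
    pa <- cfg$post_onset_prob[[a]]
    if (is.na(pa)) next
    idx <- which(arch == a)
    post <- stats::runif(length(idx)) < pa
    span_post <- as.numeric(difftime(w1, onset, units = "secs"))
    span_pre <- as.numeric(difftime(onset, w0, units = "secs"))
    submitted[idx[post]] <- onset + stats::runif(sum(post), 1, max(span_post, 2))
    submitted[idx[!post]] <- w0 + stats::runif(sum(!post), 0, max(span_pre, 1))
  }

  # bot submission waves sharing an IP, consecutive gaps <= window_s
  if (!is.null(cfg$batch)) {
    bot_idx <- which(arch == "bot")
    nw <- cfg$batch$n_waves
    ws <- cfg$batch$wave_size
    slots <- min(length(bot_idx), nw * ws)
    if (slots >= 2 && nw >= 1) {
      chosen <- sample(bot_idx, slots)
      wave_of <- rep(seq_len(nw), each = ws, length.out = slots)
      for (wv in seq_len(nw)) {
        members <- chosen[wave_of == wv]
        if (length(members) < 2) next
        span <- as.numeric(difftime(w1, onset, units = "secs"))
        start <- onset + stats::runif(1, 1, max(span * 0.8, 2))
        gaps <- stats::runif(length(members) - 1, 1,
                             max(cfg$batch$window_s * 0.9, 2))
        submitted[members] <- start + c(0, cumsum(gaps))
        ip[members] <- r_ip(1)
      }
    }
  }

  # whole-second instants so flat-file round trips are lossless
  submitted <- as.POSIXct(round(as.numeric(submitted)),
                          origin = "1970-01-01", tz = "UTC")
  started <- submitted - dur

  # duplicator identity groups: shared name/email/phone/ip
  dup_idx <- which(arch == "duplicator")
  if (length(dup_idx) >= 2) {
    lo <- cfg$duplicate_multiplicity[1]
    hi <- cfg$duplicate_multiplicity[2]
    i <- 1
    while (i <= length(dup_idx)) {
      size <- min(sample(lo:hi, 1), length(dup_idx) - i + 1)
      members <- dup_idx[i:(i + size - 1)]
      head_m <- members[1]
      first[members] <- first[head_m]
      last[members] <- last[head_m]
      phone[members] <- phone[head_m]
      ip[members] <- ip[head_m]
      i <- i + size
    }
  }

  # emails: concordant with the name, or an alias/pattern local part
  concordant <- stats::runif(n) < p_of("email_concordance_prob")
  email <- character(n)
  for (i in seq_len(n)) {
    email[i] <- if (concordant[i]) {
      r_concordant_email(first[i], last[i], cfg$trusted_domain_prob)
    } else if (arch[i] %in% c("bot", "misrepresenter")) {
      r_pattern_email()
    } else {
      r_alias_email()
    }
  }
  # group email shared within duplicator groups (same person re-entering)
  if (length(dup_idx) >= 2) {
    for (ph in unique(phone[dup_idx])) {
      members <- dup_idx[phone[dup_idx] == ph]
      email[members] <- email[members[1]]
    }
  }

  honeypot <- ifelse(stats::runif(n) < p_of("honeypot_prob"),
                     sample(c("x", "1", "yes", "asdf"), n, replace = TRUE),
                     "")
  captcha <- numeric(n)
  for (a in .archetypes) {
    idx <- which(arch == a)
    ab <- cfg$captcha_beta[[a]]
    captcha[idx] <- stats::rbeta(length(idx), ab[1], ab[2])
  }
  captcha[stats::runif(n) < cfg$captcha_missing_prob] <- NA_real_
  attempts <- 1L + ifelse(stats::runif(n) < p_of("multi_attempt_prob"),
                          1L + stats::rpois(n, 0.7), 0L)
  remun <- stats::runif(n) < p_of("remuneration_request_prob")
  registry <- rep(NA, n)
  looked_up <- stats::runif(n) < 0.3
  registry[looked_up] <- arch[looked_up] %in% c("genuine", "duplicator")

  # answers
  specialty <- sample(c("family_medicine", "obgyn", "mfm_subspecialist",
                        "nurse_practitioner"), n, replace = TRUE,
                      prob = c(0.45, 0.30, 0.10, 0.15))
  college_map <- c(family_medicine = "CFPC", obgyn = "RCPSC",
                   mfm_subspecialist = "RCPSC", nurse_practitioner = "CNA")
  college <- unname(college_map[specialty])
  inconsistent <- stats::runif(n) < p_of("inconsistent_answer_prob")
  for (i in which(inconsistent)) {
    if (stats::runif(1) < 0.6) {
      specialty[i] <- "mfm_subspecialist"; college[i] <- "CFPC"
    } else {
      specialty[i] <- "nurse_practitioner"; college[i] <- "RCPSC"
    }
  }
  years <- round(stats::runif(n, 1, 40))
  lik <- matrix(sample(1:5, 3 * n, replace = TRUE), ncol = 3)
  straight <- stats::runif(n) < p_of("straightline_prob")
  lik[straight, ] <- sample(1:5, sum(straight), replace = TRUE)

  plausible <- stats::runif(n) < p_of("freetext_plausibility_prob")
  ft <- character(n)
  for (i in seq_len(n)) {
    ft[i] <- if (plausible[i]) r_sentence(sample(8:14, 1)) else r_garbage_text()
  }

  ord <- order(started, seq_len(n))
  recs <- data.frame(
    record_id = sprintf("r%05d", seq_len(n)),
    started_at = started[ord], submitted_at = submitted[ord],
    duration_s = dur[ord],
    email = email[ord],
    name = paste(toupper(substring(first[ord], 1, 1)),
                 substring(first[ord], 2), sep = ""),
    phone = phone[ord], postcode = postcode[ord], ip = ip[ord],
    remuneration_requested = remun[ord], captcha_score = captcha[ord],
    honeypot_value = honeypot[ord], screening_attempts = attempts[ord],
    registry_verified = registry[ord], truth_archetype = arch[ord],
    specialty = specialty[ord], college = college[ord],
    years_practice = years[ord],
    q_likert1 = lik[ord, 1], q_likert2 = lik[ord, 2], q_likert3 = lik[ord, 3],
    ft_other_services = ft[ord],
    stringsAsFactors = FALSE
  )
  recs$name <- paste(recs$name, paste0(toupper(substring(last[ord], 1, 1)),
                                       substring(last[ord], 2)))
  # clamp onset into the realized record window (degenerate prevalences can
  # otherwise push every submission past the nominal onset)
  onset_eff <- min(max(onset, min(recs$started_at)),
                   max(recs$submitted_at) + 86400)
  ds <- survey_dataset(recs, schema = default_schema(),
                       fraud_onset_date = onset_eff)
  attr(ds, "latent") <- data.frame(record_id = recs$record_id,
                                   freetext_plausible = plausible[ord],
                                   stringsAsFactors = FALSE)
  attr(ds, "config") <- cfg
  ds
}

#' Append a batch-submission fraud wave to a dataset
#'
#' Adds `size` bot-archetype records whose consecutive submission instants
#' are at most `window_s` seconds apart and which all share one identifier
#' value (`email`, `phone`, or `ip`), the signature of a same-account batch
#' influx. Record count grows by exactly `size`.
#'
#' @param dataset a [survey_dataset()].
#' @param wave list with `start` (timestamp inside the dataset window),
#'   `size` (>= 2), `shared_key` (one of `"email"`, `"phone"`, `"ip"`),
#'   and optional `window_s` (maximum consecutive gap, default 300).
#' @param seed optional integer; when given the wave is generated under a
#'   local seed and reproducible.
#' @return the augmented `survey_dataset`.
#' @export
inject_fraud_wave <- function(dataset, wave, seed = NULL) {
  stopifnot(inherits(dataset, "survey_dataset"))
  size <- wave$size %||% 0
  if (size < 2) stopf("wave size must be >= 2 (got %s)", size)
  key <- wave$shared_key %||% "ip"
  if (!key %in% c("email", "phone", "ip")) {
    stopf("shared_key must be an identifier field (email, phone, ip), got '%s'",
          key)
  }
  start <- parse_utc(wave$start)
  if (is.na(start)) stopf("wave start could not be parsed")
  recs <- dataset$records
  if (nrow(recs) > 0) {
    lo <- min(recs$started_at, na.rm = TRUE)
    hi <- max(recs$submitted_at, na.rm = TRUE) + 86400
    if (start < lo || start > hi) {
      stopf("wave start %s outside the dataset window", format_utc(start))
    }
  }
  window_s <- wave$window_s %||% 300
  gen <- function() {
    gaps <- stats::runif(size - 1, 1, max(window_s - 1, 1.5))
    submitted <- start + c(0, cumsum(gaps))
    submitted <- as.POSIXct(round(as.numeric(submitted)),
                            origin = "1970-01-01", tz = "UTC")
    dur <- round(stats::runif(size, 30, 300))
    k <- nrow(recs)
    new <- empty_records(size)
    new$record_id <- sprintf("w%05d", k + seq_len(size))
    new$submitted_at <- submitted
    new$started_at <- submitted - dur
    new$duration_s <- dur
    shared <- switch(key,
      email = paste0("batch", k, "@", sample(.suspicious_domains, 1)),
      phone = r_phone(1),
      ip = r_ip(1))
    new[[key]] <- shared
    others <- setdiff(c("email", "phone", "ip"), key)
    for (f in others) {
      new[[f]] <- switch(f, email = vapply(seq_len(size),
                                           function(i) r_pattern_email(),
                                           character(1)),
                         phone = r_phone(size), ip = r_ip(size))
    }
    new$name <- paste(sample(.first_names, size, replace = TRUE),
                      sample(.last_names, size, replace = TRUE))
    new$postcode <- sprintf("%04d", sample(800:7999, size, replace = TRUE))
    new$remuneration_requested <- TRUE
    new$captcha_score <- stats::rbeta(size, 2, 8)
    new$honeypot_value <- ifelse(stats::runif(size) < 0.9, "x", "")
    new$screening_attempts <- 1L + stats::rpois(size, 0.8)
    new$truth_archetype <- "bot"
    for (q in question_ids(dataset$schema)) {
      dom <- dataset$schema$questions[[q]]
      new[[q]] <- if (identical(dom, "numeric")) {
        sample(1:5, size, replace = TRUE)
      } else if (q %in% dataset$schema$free_text) {
        vapply(seq_len(size), function(i) r_garbage_text(), character(1))
      } else {
        sample(dom, size, replace = TRUE)
      }
    }
    new
  }
  new <- if (is.null(seed)) gen() else with_seed(seed, gen())
  out <- dataset
  common <- intersect(names(recs), names(new))
  out$records <- rbind(recs[, common, drop = FALSE],
                       new[, common, drop = FALSE])
  lat <- attr(dataset, "latent")
  if (!is.null(lat)) {
    attr(out, "latent") <- rbind(lat, data.frame(
      record_id = new$record_id, freetext_plausible = FALSE,
      stringsAsFactors = FALSE))
  }
  attr(out, "config") <- attr(dataset, "config")
  out
}
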