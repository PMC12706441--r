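test_that("criterion construction enforces the sign convention", {
  expect_error(criterion("x", "protective", 2, "honeypot"), "negative")
  expect_error(criterion("x", "suspicious", -2, "honeypot"), "positive")
  expect_error(criterion("x", "suspicious", 0, "honeypot"), "non-zero")
  expect_error(criterion("x", "suspicious", 2, "psychic"), "unknown evaluator")
})

test_that("duplicate grouping retains the earliest start and matches the pairwise oracle", {
  recs <- data.frame(
    record_id = c("d1", "d2", "d3"),
    started_at = c("2020-09-02T10:00:00Z", "2020-09-01T10:00:00Z",
                   "2020-09-03T10:00:00Z"),
    email = c("A@x.org ", "a@x.org", "b@y.org"),
    stringsAsFactors = FALSE)
  ds <- survey_dataset(recs)
  g <- find_duplicates(ds, "email")
  expect_equal(nrow(g), 2)
  expect_equal(g$record_id[g$retain], "d2")  # earlier start retained

  recs$email <- c("a@x.org", "b@y.org", "c@z.org")
  expect_equal(nrow(find_duplicates(survey_dataset(recs), "email")), 0)

  expect_error(find_duplicates(ds, "specialty"), "identifier")

  # randomized datasets against the O(n^2) oracle, including cross-key links
  set.seed(31)
  for (rep in 1:5) {
    n <- 60
    recs <- data.frame(
      record_id = sprintf("x%02d", 1:n),
      started_at = format(as.POSIXct("2020-09-01", tz = "UTC") +
                            sample(1:5e5, n), "%Y-%m-%dT%H:%M:%SZ"),
      email = sample(c(sprintf("e%d@x.org", 1:12), NA), n, replace = TRUE),
      phone = sample(c(sprintf("04%07d", 1:15), NA), n, replace = TRUE),
      stringsAsFactors = FALSE)
    ds <- survey_dataset(recs)
    got <- find_duplicates(ds, c("email", "phone"))
    want <- oracle_duplicates(ds$records, c("email", "phone"))
    expect_setequal(got$record_id, want$in_group)
    expect_setequal(got$record_id[!got$retain], want$duplicates)
  }
})

test_that("email pattern flag follows the stated rule", {
  expect_false(email_pattern_flag("jane.smith@hospital.ca", "Jane Smith"))
  expect_true(email_pattern_flag("9823471265@mail.com", "Whoever"))
  expect_true(email_pattern_flag("q1w2e3r4@mail.com", "Bob Lee"))
  expect_false(email_pattern_flag("jsmith77@gmail.com", "Jane Smith"))
  expect_true(email_pattern_flag("no-at-sign", "Jane Smith"))  # malformed
  expect_false(email_pattern_flag(NA, "Jane Smith"))

  # random (email, name) pairs against the rule oracle
  set.seed(44)
  locals <- c("jane.smith", "q1w2e3r4ty5", "883726151", "sunny42",
              "ab1cd2ef3", "taylor9", "x9y8z7w6", "greenhill", "m4k2",
              "robert.jones12", "12345678", "a1b2c3d4e5f6")
  names_pool <- c("Jane Smith", "Robert Jones", "Mei Wu", "Sunny Green",
                  "Taylor King", NA)
  for (i in 1:200) {
    em <- paste0(sample(locals, 1), "@", sample(c("x.org", "mail.com"), 1))
    nm <- sample(names_pool, 1)
    expect_equal(email_pattern_flag(em, nm), oracle_email(em, nm),
                 label = paste(em, nm))
  }
})

test_that("completion-time flag is strict at the threshold", {
  expect_true(completion_time_flag(799, 800))
  expect_false(completion_time_flag(800, 800))
  expect_true(completion_time_flag(299, 300))
  expect_false(completion_time_flag(300, 300))
})

test_that("batch detection equals exhaustive run enumeration", {
  mk <- function(times, key = NULL) {
    recs <- data.frame(
      record_id = sprintf("b%03d", seq_along(times)),
      submitted_at = format(as.POSIXct("2021-08-01", tz = "UTC") + times,
                            "%Y-%m-%dT%H:%M:%SZ"),
      stringsAsFactors = FALSE)
    if (!is.null(key)) recs$email <- key
    survey_dataset(recs)
  }
  ds <- mk(seq(0, by = 60, length.out = 5))
  expect_setequal(batch_flag(ds, 120, 3), ds$records$record_id)
  ds <- mk(seq(0, by = 500, length.out = 5))
  expect_length(batch_flag(ds, 120, 3), 0)
  expect_error(batch_flag(ds, 120, 1), ">= 2")

  set.seed(77)
  for (rep in 1:5) {
    n <- 80
    times <- sort(sample(1:5000, n))
    keys <- sample(sprintf("k%d@x.org", 1:4), n, replace = TRUE)
    ds <- mk(times, keys)
    for (sk in list(NULL, "email")) {
      got <- batch_flag(ds, window_s = 90, min_count = 4, shared_key = sk)
      want <- oracle_batch(ds$records$record_id, ds$records$submitted_at,
                           90, 4,
                           if (is.null(sk)) NULL else ds$records$email)
      expect_setequal(got, want)
    }
  }
})

test_that("consistency rules fire exactly when their clause conjunction holds", {
  rec <- list(specialty = "mfm_subspecialist", college = "CFPC")
  expect_equal(consistency_violations(rec, default_consistency_rules()),
               "mfm_cfpc")
  expect_length(consistency_violations(rec, list()), 0)

  set.seed(52)
  fields <- c("a", "b", "c")
  ops <- c("eq", "ne", "lt", "le", "gt", "ge")
  for (i in 1:100) {
    rec <- list(a = sample(1:4, 1), b = sample(1:4, 1), c = sample(1:4, 1))
    rules <- lapply(1:3, function(j) {
      cls <- lapply(1:sample(1:2, 1), function(k) {
        list(field = sample(fields, 1), op = sample(ops, 1),
             value = sample(1:4, 1))
      })
      consistency_rule(paste0("rule", j), cls)
    })
    manual <- vapply(rules, function(r) {
      all(vapply(r$clauses, function(cl) {
        v <- rec[[cl$field]]
        switch(cl$op, eq = v == cl$value, ne = v != cl$value,
               lt = v < cl$value, le = v <= cl$value,
               gt = v > cl$value, ge = v >= cl$value)
      }, logical(1)))
    }, logical(1))
    want <- if (any(manual)) paste0("rule", which(manual)) else character()
    expect_setequal(consistency_violations(rec, rules), want)
  }

  # unknown fields are a config error at registry load, not evaluation
  bad <- list(consistency_rule("ghost", list(
    list(field = "nonexistent", op = "eq", value = 1))))
  ds <- tiny_dataset()
  expect_error(
    evaluate_criteria(ds, list(criterion("combo", "suspicious", 3,
                                         "consistency",
                                         list(rules = bad)))),
    "unknown field")
})

test_that("free-text protectiveness recovers the generator's latent labels", {
  expect_true(freetext_protective(
    c(ft = "I also provide procedural abortion at a second clinic")))
  expect_false(freetext_protective(character()))
  expect_false(freetext_protective(c(ft = "")))
  expect_false(freetext_protective(c(ft = "good good good")))
  expect_false(freetext_protective(c(ft = "xkcdq zpfmg qwrtz bnmpl vczls")))
  # verbatim duplication across records disqualifies
  txt <- "We offer telehealth consults for rural patients each week"
  expect_true(freetext_protective(c(ft = txt),
                                  corpus = list(ft = c(txt, "other"))))
  expect_false(freetext_protective(c(ft = txt),
                                   corpus = list(ft = c(txt, txt))))

  ds <- generate_cohort(cohort_preset("case1_like", n_records = 800,
                                      seed = 14))
  res <- evaluate_criteria(ds, list(criterion("ft", "protective", -3,
                                              "freetext")))
  latent <- attr(ds, "latent")
  agree <- mean(res$fired[latent$record_id, "ft"] == latent$freetext_plausible)
  expect_gte(agree, 0.95)
})

test_that("bot, remuneration, onset, and screening flags follow their boundary conventions", {
  expect_equal(bot_flags(list(honeypot_value = "", captcha_score = 0.9)),
               list(honeypot_fired = FALSE, captcha_fired = FALSE))
  expect_true(bot_flags(list(honeypot_value = "abc",
                             captcha_score = 0.9))$honeypot_fired)
  expect_true(bot_flags(list(honeypot_value = "",
                             captcha_score = 0.49))$captcha_fired)
  expect_false(bot_flags(list(honeypot_value = "",
                              captcha_score = 0.5))$captcha_fired)

  expect_equal(remuneration_flag(list(remuneration_requested = FALSE)),
               "protective")
  expect_equal(remuneration_flag(list(remuneration_requested = TRUE)),
               "neutral")

  onset <- as.POSIXct("2020-10-06", tz = "UTC")
  expect_equal(onset_flag(list(submitted_at = "2020-09-01T10:00:00Z"), onset),
               "protective")
  expect_equal(onset_flag(list(submitted_at = "2020-10-06T00:00:00Z"), onset),
               "suspicious")
  expect_equal(onset_flag(list(submitted_at = "2020-09-01T10:00:00Z"), NULL),
               "none")

  expect_false(screening_attempts_flag(list(screening_attempts = 0L)))
  expect_false(screening_attempts_flag(list(screening_attempts = 1L)))
  expect_true(screening_attempts_flag(list(screening_attempts = 2L)))
})

test_that("evaluation produces a full matrix whose totals match independent summation", {
  ds <- tiny_dataset()
  reg <- criteria_preset("case1")
  res <- evaluate_criteria(ds, reg)
  expect_equal(dim(res$fired), c(3, length(reg)))
  expect_equal(length(res$fired), 3 * length(reg))

  pts <- vapply(reg, `[[`, numeric(1), "points")
  manual <- apply(res$fired, 1, function(r) sum(pts[r]))
  expect_equal(unname(total_score(res)), unname(manual))

  # purity: repeated evaluation is identical
  expect_identical(res$fired, evaluate_criteria(ds, reg)$fired)

  # no remuneration requested anywhere -> zero protective points from it
  ds2 <- ds
  ds2$records$remuneration_requested <- TRUE
  res2 <- evaluate_criteria(ds2, list(criterion("no_remun", "protective",
                                               -1, "no_remuneration")))
  expect_equal(sum(res2$points), 0)
})

test_that("scores are monotone in registry growth", {
  ds <- generate_cohort(cohort_preset("case1_like", n_records = 120, seed = 6))
  base <- criteria_preset("case1")
  s0 <- total_score(evaluate_criteria(ds, base))
  s_plus <- total_score(evaluate_criteria(
    ds, c(base, list(criterion("extra_susp", "suspicious", 2,
                               "screening_attempts")))))
  expect_true(all(s_plus >= s0))
  s_minus <- total_score(evaluate_criteria(
    ds, c(base, list(criterion("extra_prot", "protective", -1,
                               "no_remuneration")))))
  expect_true(all(s_minus <= s0))
})

test_that("on a separable cohort the honeypot criterion alone is perfect", {
  ds <- generate_cohort(cohort_preset("case1_like_separable",
                                      n_records = 500, seed = 19))
  res <- evaluate_criteria(ds, list(criterion("hp", "suspicious", 4,
                                              "honeypot")))
  truth <- ds$records$truth_archetype
  fired <- res$fired[, "hp"]
  expect_true(all(fired[truth == "bot"]))       # sensitivity 1 on bots
  expect_false(any(fired[truth == "genuine"]))  # specificity 1 on genuine
})

test_that("criteria registries round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "criteria:",
    "  - name: fast",
    "    direction: suspicious",
    "    points: 2",
    "    evaluator: completion_time",
    "    params: {threshold_s: 300}",
    "  - name: combo",
    "    direction: suspicious",
    "    points: 3",
    "    evaluator: consistency",
    "  - name: freetext",
    "    direction: protective",
    "    points: -3",
    "    evaluator: freetext",
    "rules:",
    "  - name: mfm_cfpc",
    "    clauses:",
    "      - {field: specialty, op: eq, value: mfm_subspecialist}",
    "      - {field: college, op: eq, value: CFPC}"), path)
  reg <- read_criteria_yaml(path)
  expect_length(reg$criteria, 3)
  expect_equal(reg$criteria[[1]]$params$threshold_s, 300)
  res <- evaluate_criteria(tiny_dataset(), reg$criteria)
  expect_true(res$fired["r3", "combo"])   # the nonsensical combination
  expect_false(res$fired["r3", "fast"])   # exactly 300 s: strict boundary
  expect_false(res$fired["r1", "combo"])
  expect_true(res$fired["r1", "freetext"])
})
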