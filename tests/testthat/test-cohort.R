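test_that("config validation rejects impossible cohorts", {
  expect_error(cohort_config(prevalence = c(genuine = 0.5, bot = 0.4)),
               "sum")
  expect_error(cohort_config(n_records = 0), "positive")
  expect_error(cohort_config(honeypot_prob = c(genuine = 0, duplicator = 0,
                                               misrepresenter = 0, bot = 1.2)),
               "\\[0, 1\\]")
  expect_error(cohort_config(batch = list(n_waves = 1, wave_size = 1,
                                          window_s = 60)), "wave_size")
})

test_that("degenerate all-genuine prevalence yields only genuine humans", {
  cfg <- cohort_config(n_records = 200,
                       prevalence = c(genuine = 1, duplicator = 0,
                                      misrepresenter = 0, bot = 0),
                       seed = 3)
  ds <- generate_cohort(cfg)
  expect_equal(nrow(ds$records), 200)
  expect_true(all(ds$records$truth_archetype == "genuine"))
  expect_true(all(ds$records$honeypot_value == ""))
})

test_that("archetype counts follow the binomial oracle", {
  cfg <- cohort_config(n_records = 1000,
                       prevalence = c(genuine = 0.55, duplicator = 0,
                                      misrepresenter = 0, bot = 0.45),
                       seed = 17)
  ds <- generate_cohort(cfg)
  n_bot <- sum(ds$records$truth_archetype == "bot")
  expect_lt(abs(n_bot - 450), 3 * sqrt(1000 * 0.45 * 0.55))
})

test_that("generation is a pure function of (config, seed)", {
  cfg <- cohort_preset("case1_like", n_records = 150, seed = 8)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_responses(generate_cohort(cfg), f1, include_truth = TRUE)
  write_responses(generate_cohort(cfg), f2, include_truth = TRUE)
  expect_identical(readLines(f1), readLines(f2))

  # and the caller's RNG stream is left untouched
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_cohort(cfg))
  expect_identical(runif(1), before)
})

test_that("label-conditional signal rates match the config within 3 binomial SD", {
  cfg <- cohort_preset("case1_like", n_records = 1500, seed = 21)
  ds <- generate_cohort(cfg)
  recs <- ds$records
  check_rate <- function(observed_k, n, p, what) {
    expect_lt(abs(observed_k - n * p), 3 * sqrt(n * p * (1 - p)) + 1e-9,
              label = what)
  }
  bots <- recs[recs$truth_archetype == "bot", ]
  check_rate(sum(nzchar(bots$honeypot_value)), nrow(bots), 0.90,
             "bot honeypot rate")
  expect_true(all(bots$duration_s < 800))  # sub-threshold bot durations
  mis <- recs[recs$truth_archetype == "misrepresenter", ]
  incons <- sum(vapply(seq_len(nrow(mis)), function(i) {
    length(consistency_violations(mis[i, ], default_consistency_rules())) > 0
  }, logical(1)))
  check_rate(incons, nrow(mis), 0.90, "misrepresenter inconsistency rate")
  # duplicators share an identifier within multiplicity groups
  dup <- recs[recs$truth_archetype == "duplicator", ]
  expect_gt(sum(duplicated(dup$email)), 0)
})

test_that("separable config gives email-pattern specificity 1 on genuine records", {
  ds <- generate_cohort(cohort_preset("case1_like_separable",
                                      n_records = 600, seed = 9))
  gen <- ds$records[ds$records$truth_archetype == "genuine", ]
  flags <- email_pattern_flag(gen$email, gen$name)
  expect_false(any(flags))
  bots <- ds$records[ds$records$truth_archetype == "bot", ]
  expect_true(all(nzchar(bots$honeypot_value)))
})

test_that("fraud waves append tightly spaced records sharing one identifier", {
  ds <- generate_cohort(cohort_preset("case1_like", n_records = 80, seed = 4))
  n0 <- nrow(ds$records)
  mid <- ds$records$submitted_at[40]
  out <- inject_fraud_wave(ds, list(start = mid, size = 10,
                                    shared_key = "ip", window_s = 300),
                           seed = 6)
  expect_equal(nrow(out$records), n0 + 10)
  new <- out$records[(n0 + 1):(n0 + 10), ]
  expect_equal(length(unique(new$ip)), 1)
  gaps <- diff(sort(as.numeric(new$submitted_at)))
  expect_true(all(gaps <= 300))

  expect_error(inject_fraud_wave(ds, list(start = mid, size = 0)), ">= 2")
  expect_error(inject_fraud_wave(ds, list(start = mid, size = 5,
                                          shared_key = "specialty")),
               "identifier")
})

test_that("a multi-day same-account influx is caught by the batch detector", {
  ds <- generate_cohort(cohort_config(
    n_records = 120, window_start = "2021-07-19", window_days = 30,
    prevalence = c(genuine = 1, duplicator = 0, misrepresenter = 0, bot = 0),
    batch = NULL, seed = 12))
  start <- min(ds$records$submitted_at) + 86400
  # 300 responses over 4 days from one email account
  out <- inject_fraud_wave(ds, list(start = start, size = 300,
                                    shared_key = "email",
                                    window_s = 4 * 86400 / 300), seed = 2)
  flagged <- batch_flag(out, window_s = 1200, min_count = 10,
                        shared_key = "email")
  expect_gt(length(flagged), 0)
  expect_true(all(grepl("^w", flagged)))
})
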