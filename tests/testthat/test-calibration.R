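test_that("control designation follows the email rules and flags conflicts", {
  recs <- data.frame(
    record_id = c("c1", "c2", "c3", "c4"),
    email = c("a@ubc.ca", "q1w2e3r4@mail.com", "plain@gmail.com", NA),
    stringsAsFactors = FALSE)
  ds <- survey_dataset(recs)
  lab <- designate_controls(ds)
  expect_equal(unname(lab), c("negative", "positive", "unlabeled",
                              "unlabeled"))

  # trusted domain AND suspicious pattern -> unlabeled with a warning
  recs$email[1] <- "q1w2e3r4@ubc.ca"
  expect_warning(lab <- designate_controls(survey_dataset(recs)), "both")
  expect_equal(unname(lab[1]), "unlabeled")

  expect_error(designate_controls(ds, control_rules(
    negative_email_domains = character())), "calibration impossible")
})

test_that("criterion performance reproduces hand-computed confusion ratios", {
  labels <- c(rep("positive", 10), rep("negative", 10))
  fired <- c(rep(TRUE, 10), rep(FALSE, 10))
  perf <- criterion_performance(fired, labels, "suspicious")
  expect_equal(perf$sensitivity, 1.0)
  expect_equal(perf$specificity, 1.0)

  # 51 of 55 positives caught: sensitivity 92.7%
  labels <- c(rep("positive", 55), rep("negative", 20))
  fired <- c(rep(TRUE, 51), rep(FALSE, 4), rep(FALSE, 20))
  perf <- criterion_performance(fired, labels, "suspicious")
  expect_equal(perf$TP, 51)
  expect_equal(perf$FN, 4)
  expect_equal(round(100 * perf$sensitivity, 1), 92.7)

  # protective polarity is inverted: not firing detects fraud
  perf <- criterion_performance(!fired, labels, "protective")
  expect_equal(perf$TP, 51)
  expect_equal(round(100 * perf$sensitivity, 1), 92.7)

  expect_error(criterion_performance(fired, rep("negative", 75),
                                     "suspicious"), "no positive")
  expect_error(criterion_performance(fired, rep("positive", 75),
                                     "suspicious"), "no negative")
})

test_that("confusion counts equal brute-force tabulation on random fixtures", {
  set.seed(61)
  for (i in 1:300) {
    n <- sample(10:60, 1)
    labels <- sample(c("positive", "negative", "unlabeled"), n,
                     replace = TRUE)
    if (!any(labels == "positive")) labels[1] <- "positive"
    if (!any(labels == "negative")) labels[2] <- "negative"
    fired <- sample(c(TRUE, FALSE), n, replace = TRUE)
    dir <- sample(c("suspicious", "protective"), 1)
    got <- criterion_performance(fired, labels, dir)
    want <- oracle_tabulate(fired, labels, dir)
    expect_equal(got$TP, want$TP)
    expect_equal(got$FP, want$FP)
    expect_equal(got$TN, want$TN)
    expect_equal(got$FN, want$FN)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$specificity, want$specificity)
  }
})

test_that("order of records does not change calibration", {
  ds <- generate_cohort(cohort_preset("case1_like", n_records = 200, seed = 2))
  reg <- criteria_preset("case1")
  res <- evaluate_criteria(ds, reg)
  lab <- truth_controls(ds)
  t1 <- calibrate(res, lab)
  perm <- sample(nrow(ds$records))
  res2 <- res
  res2$fired <- res$fired[perm, ]
  res2$points <- res$points[perm, ]
  t2 <- calibrate(res2, lab)
  expect_equal(t1, t2)
})

test_that("threshold selection separates separable controls and flags degeneracy", {
  scores <- c(rep(-5, 20), rep(5, 20))
  labels <- c(rep("negative", 20), rep("positive", 20))
  thr <- select_thresholds(scores, labels,
                           list(min_specificity = 0.95,
                                min_sensitivity = 0.95))
  expect_lte(thr$low_cut, thr$high_cut)
  expect_false(thr$degenerate)
  b <- assign_bucket(scores, thr)
  expect_true(all(b[labels == "negative"] == "INCLUDE"))
  expect_true(all(b[labels == "positive"] == "EXCLUDE"))

  # all controls at one score: degenerate, cuts collapse
  expect_warning(
    thr <- select_thresholds(rep(3, 10),
                             c(rep("positive", 5), rep("negative", 5))),
    "degenerate")
  expect_equal(thr$low_cut, thr$high_cut)

  expect_error(select_thresholds(1:3, rep("unlabeled", 3)), "control")
})

test_that("selected cuts satisfy their fraction constraints under exhaustive scan", {
  set.seed(83)
  checked <- 0
  for (i in 1:200) {
    n <- sample(20:80, 1)
    scores <- sample(-5:10, n, replace = TRUE)
    labels <- sample(c("positive", "negative"), n, replace = TRUE,
                     prob = c(0.5, 0.5))
    if (!any(labels == "positive")) labels[1] <- "positive"
    if (!any(labels == "negative")) labels[2] <- "negative"
    targets <- list(min_specificity = runif(1, 0.7, 0.99),
                    min_sensitivity = runif(1, 0.7, 0.99))
    warned <- FALSE
    thr <- withCallingHandlers(
      select_thresholds(scores, labels, targets),
      warning = function(w) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    expect_lte(thr$low_cut, thr$high_cut)
    if (warned) next
    checked <- checked + 1
    pos <- scores[labels == "positive"]
    neg <- scores[labels == "negative"]
    expect_lte(mean(neg >= thr$high_cut), 1 - targets$min_specificity)
    expect_lte(mean(pos <= thr$low_cut), 1 - targets$min_sensitivity)
    # optimality over an exhaustive scan of observed candidate cuts
    cand <- sort(unique(scores))
    hi_ok <- cand[vapply(cand, function(s)
      mean(neg >= s) <= 1 - targets$min_specificity, logical(1))]
    lo_ok <- cand[vapply(cand, function(s)
      mean(pos <= s) <= 1 - targets$min_sensitivity, logical(1))]
    expect_equal(thr$high_cut, min(hi_ok))
    expect_equal(thr$low_cut, max(lo_ok[lo_ok <= min(hi_ok)]))
  }
  expect_gt(checked, 20)
})

test_that("raising the specificity target never lowers the exclude cut", {
  set.seed(90)
  scores <- c(rnorm(60, -3, 2), rnorm(60, 6, 2))
  labels <- c(rep("negative", 60), rep("positive", 60))
  cuts <- vapply(c(0.80, 0.90, 0.95, 0.99), function(ms) {
    suppressWarnings(select_thresholds(
      scores, labels, list(min_specificity = ms,
                           min_sensitivity = 0.85)))$high_cut
  }, numeric(1))
  expect_true(all(diff(cuts) >= 0))
})

test_that("truth labels as controls agree with direct truth tabulation", {
  ds <- generate_cohort(cohort_preset("case1_like", n_records = 400,
                                      seed = 23))
  reg <- criteria_preset("case1")
  res <- evaluate_criteria(ds, reg)
  tab <- calibrate(res, truth_controls(ds))
  truth <- ds$records$truth_archetype
  labels <- ifelse(truth == "genuine", "negative",
                   ifelse(truth == "bot", "positive", "unlabeled"))
  for (j in seq_along(reg)) {
    want <- oracle_tabulate(res$fired[, j], labels, reg[[j]]$direction)
    expect_equal(tab$sensitivity[j], want$sensitivity)
    expect_equal(tab$specificity[j], want$specificity)
  }
})
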